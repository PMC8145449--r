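# Model fitting: FDR screening -> forward-backward stepwise AIC ->
# significance trimming -> favorability surface.

model_frame <- function(occurrence, landscape) {
  stopifnot(inherits(occurrence, "species_occurrence"),
            inherits(landscape, "grid_landscape"))
  if (!identical(occurrence$cell_id, which(landscape$valid)))
    stop("occurrence and landscape are not on the same grid")
  df <- as.data.frame(landscape)
  df$.y <- occurrence$presence
  df
}

check_two_classes <- function(occurrence) {
  if (occurrence$n1 == 0 || occurrence$n0 == 0)
    stop("degenerate response: species has only one class (n1 = ",
         occurrence$n1, ", n0 = ", occurrence$n0, ")")
}

#' Benjamini-Hochberg acceptance set
#'
#' Step-up FDR rule: with ordered p-values p(1) <= ... <= p(m), find the
#' largest k with p(k) <= k q / m and accept all tests with p <= p(k).
#' Equivalent to `p.adjust(p, "BH") <= q`, which is how it is computed.
#'
#' @param p_values raw p-values.
#' @param q FDR level.
#' @return logical vector: accepted (significant under FDR q)?
#' @export
bh_select <- function(p_values, q = 0.05) {
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Univariate predictor screening under FDR control
#'
#' Fits one single-predictor logistic regression per layer, takes the
#' likelihood-ratio p-value against the intercept-only model, and accepts
#' the Benjamini-Hochberg step-up set at level `q`.  Screening keeps the
#' later stepwise search honest when many (possibly correlated) candidate
#' predictors are on offer.
#'
#' @param occurrence a [species_occurrence] with at least one presence and
#'   one absence.
#' @param landscape the matching [grid_landscape].
#' @param q FDR level (default 0.05).
#' @return a `screening_result`: data.frame `table` (predictor, `p_value`,
#'   `p_adjusted`, `accepted`) plus `q` and the accepted names.
#' @export
univariate_screen <- function(occurrence, landscape, q = 0.05) {
  check_two_classes(occurrence)
  df <- model_frame(occurrence, landscape)
  pnames <- names(landscape$predictors)
  null_dev <- suppressWarnings(
    stats::glm(.y ~ 1, family = stats::binomial(), data = df))$deviance
  p <- vapply(pnames, function(nm) {
    fit <- suppressWarnings(stats::glm(
      stats::reformulate(nm, response = ".y"),
      family = stats::binomial(), data = df))
    stat <- max(null_dev - fit$deviance, 0)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }, numeric(1))
  acc <- bh_select(p, q)
  structure(list(
    table = data.frame(predictor = pnames, p_value = unname(p),
                       p_adjusted = stats::p.adjust(p, "BH"),
                       accepted = unname(acc), row.names = NULL),
    accepted = pnames[acc], q = q), class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("univariate screening (FDR q = %g): %d of %d predictors accepted\n",
              x$q, length(x$accepted), nrow(x$table)))
  if (length(x$accepted))
    cat("  accepted:", paste(x$accepted, collapse = ", "), "\n")
  invisible(x)
}

# ridge-stabilized logistic fit (penalized IRLS; penalty on slopes only),
# used when ML coefficients diverge under (quasi-)separation
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 200, tol = 1e-10) {
  X1 <- cbind(`(Intercept)` = 1, X)
  k <- ncol(X1)
  pen <- diag(c(0, rep(lambda, k - 1)), k)
  beta <- numeric(k)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    g <- crossprod(X1, y - mu) - 2 * pen %*% beta
    H <- crossprod(X1, X1 * w) + 2 * pen
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X1 %*% beta)
  mu <- stats::plogis(eta)
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  se <- sqrt(diag(solve(crossprod(X1, X1 * pmax(mu * (1 - mu), 1e-12)) +
                          2 * pen)))
  list(coefficients = stats::setNames(drop(beta), colnames(X1)),
       se = stats::setNames(se, colnames(X1)),
       fitted = mu, loglik = ll, aic = -2 * ll + 2 * k)
}

# fit the logistic model on `vars`, with separation fallback, and package
# it as a favorability_model (surfaces attached later)
fit_logistic_model <- function(df, vars, occurrence,
                               separation_threshold = 15,
                               ridge_lambda = 1e-4) {
  form <- stats::reformulate(if (length(vars)) vars else "1",
                             response = ".y")
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = df))
  beta <- stats::coef(fit)
  separation <- length(vars) > 0 && any(abs(beta[-1]) > separation_threshold)
  if (separation) {
    X <- as.matrix(df[vars])
    rfit <- ridge_logistic(X, df$.y, lambda = ridge_lambda)
    est <- rfit$coefficients
    se <- rfit$se
    fitted <- rfit$fitted
    aic <- rfit$aic
    engine <- "ridge"
  } else {
    sm <- summary(fit)$coefficients
    est <- stats::setNames(sm[, "Estimate"], rownames(sm))
    se <- stats::setNames(sm[, "Std. Error"], rownames(sm))
    fitted <- stats::fitted(fit)
    aic <- stats::AIC(fit)
    engine <- "glm"
  }
  z <- est / se
  pval <- 2 * stats::pnorm(-abs(z))
  slopes <- setdiff(names(est), "(Intercept)")
  structure(list(
    species_id = occurrence$species_id,
    variables = vars,
    intercept = unname(est["(Intercept)"]),
    coefficients = est[slopes],
    coefficient_z = z[slopes],
    coefficient_p = pval[slopes],
    coef_table = data.frame(term = names(est), estimate = unname(est),
                            std_error = unname(se), z = unname(z),
                            p_value = unname(pval), row.names = NULL),
    aic = aic, n1 = occurrence$n1, n0 = occurrence$n0,
    separation = separation, engine = engine,
    presence = occurrence$presence, data = df),
    class = "favorability_model")
}

#' Maximum-likelihood logistic fit of a fixed variable set
#'
#' No selection: fits exactly `variables` (possibly none, for the
#' intercept-only model).  Useful for refitting a known generative model,
#' or for building a model to hand to [trim_model()].
#'
#' @inheritParams stepwise_aic
#' @param variables predictor names to include.
#' @return a `favorability_model`.
#' @export
fit_model <- function(occurrence, landscape, variables = character(0)) {
  check_two_classes(occurrence)
  df <- model_frame(occurrence, landscape)
  bad <- setdiff(variables, names(landscape$predictors))
  if (length(bad))
    stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  fit_logistic_model(df, variables, occurrence)
}

#' Forward-backward stepwise logistic regression by AIC
#'
#' Starts from the intercept-only model.  At every iteration all
#' single-variable additions (from `predictors`) and removals are scored by
#' AIC and the best move is applied; the search stops when no move lowers
#' the current AIC.  Ties (within 1e-8) are broken by preferring removal
#' over addition, then by predictor name, so the search is deterministic.
#'
#' @param occurrence a [species_occurrence].
#' @param landscape the matching [grid_landscape].
#' @param predictors candidate predictor names (typically the accepted set
#'   of [univariate_screen()]).
#' @param trace print each move.
#' @return a `favorability_model` (maximum-likelihood fit of the selected
#'   variable set; ridge-stabilized and flagged if separation is detected).
#' @export
stepwise_aic <- function(occurrence, landscape, predictors,
                         trace = FALSE) {
  check_two_classes(occurrence)
  df <- model_frame(occurrence, landscape)
  bad <- setdiff(predictors, names(landscape$predictors))
  if (length(bad))
    stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  aic_of <- function(vars) {
    form <- stats::reformulate(if (length(vars)) vars else "1",
                               response = ".y")
    stats::AIC(suppressWarnings(
      stats::glm(form, family = stats::binomial(), data = df)))
  }
  sel <- character(0)
  cur_aic <- aic_of(sel)
  repeat {
    adds <- setdiff(predictors, sel)
    drops <- sel
    moves <- rbind(
      if (length(drops)) data.frame(type = "drop", var = drops),
      if (length(adds)) data.frame(type = "add", var = adds))
    if (is.null(moves) || nrow(moves) == 0) break
    moves$aic <- vapply(seq_len(nrow(moves)), function(i) {
      v <- moves$var[i]
      aic_of(if (moves$type[i] == "add") c(sel, v) else setdiff(sel, v))
    }, numeric(1))
    best <- min(moves$aic)
    if (cur_aic - best <= 1e-8) break
    cand <- moves[moves$aic <= best + 1e-8, , drop = FALSE]
    cand <- cand[order(cand$type != "drop", cand$var), , drop = FALSE]
    mv <- cand[1, ]
    sel <- if (mv$type == "add") c(sel, mv$var) else setdiff(sel, mv$var)
    cur_aic <- mv$aic
    if (trace)
      cat(sprintf("  %s %s -> AIC %.3f\n", mv$type, mv$var, cur_aic))
  }
  fit_logistic_model(df, sort(sel), occurrence)
}

#' Trim non-significant coefficients from a fitted model
#'
#' Iteratively refits after removing the variable with the largest Wald
#' p-value at or above `alpha`, until every remaining slope is significant.
#' Non-significance of jointly selected variables usually signals
#' multicollinearity; trimming keeps one informative representative.  The
#' intercept is never removed; the result may be intercept-only.
#'
#' @param model a `favorability_model`.
#' @param alpha Wald significance level retained variables must beat.
#' @return the trimmed `favorability_model`.
#' @export
trim_model <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "favorability_model"))
  occurrence <- structure(list(species_id = model$species_id,
                               presence = model$presence,
                               n1 = model$n1, n0 = model$n0),
                          class = "species_occurrence")
  vars <- model$variables
  repeat {
    if (length(vars) == 0) break
    p <- model$coefficient_p[vars]
    if (all(p < alpha)) break
    drop_var <- vars[which.max(p)]
    vars <- setdiff(vars, drop_var)
    model <- fit_logistic_model(model$data, vars, occurrence)
  }
  model
}

#' Fit a favorability model for one species
#'
#' The full per-species modelling chain: univariate logistic screening with
#' Benjamini-Hochberg FDR control at `q`, forward-backward stepwise
#' selection by AIC, Wald-significance trimming at `trim_alpha`, and the
#' favorability transform of the fitted probabilities (so `F = 0.5` marks
#' cells whose predicted probability equals the species' prevalence).
#'
#' @param occurrence a [species_occurrence] with both classes present.
#' @param landscape the matching [grid_landscape].
#' @param q FDR level of the screening stage.
#' @param trim_alpha Wald level of the trimming stage.
#' @return a `favorability_model` with, in addition to the coefficient
#'   table, the per-valid-cell `fitted_probability` and `favorability`
#'   surfaces, the `screening` result, and a `separation` flag.
#' @seealso [predict.favorability_model()], [evaluate_model()],
#'   [detect_patches()], [run_species()].
#' @export
#' @examples
#' cfg <- generator_config(seed = 2, n_rows = 25, n_cols = 30,
#'                         n_predictors = 4,
#'                         true_coefficients = c(env01 = 1.5))
#' land <- generate_landscape(cfg)
#' occ <- generate_species(land, cfg)
#' fit <- favorability_fit(occ, land)
#' fit
favorability_fit <- function(occurrence, landscape, q = 0.05,
                             trim_alpha = 0.05) {
  check_two_classes(occurrence)
  screening <- univariate_screen(occurrence, landscape, q = q)
  model <- stepwise_aic(occurrence, landscape, screening$accepted)
  model <- trim_model(model, alpha = trim_alpha)
  model$screening <- screening
  model$grid <- list(n_rows = landscape$n_rows, n_cols = landscape$n_cols,
                     valid = landscape$valid,
                     cell_size = landscape$cell_size)
  model$fitted_probability <- predict(model, type = "probability")
  model$favorability <- favorability(model$fitted_probability,
                                     model$n1, model$n0)
  model
}

#' @export
print.favorability_model <- function(x, ...) {
  cat(sprintf("favorability model '%s' (%s fit%s)\n", x$species_id,
              x$engine, if (x$separation) ", separation flagged" else ""))
  cat(sprintf("  n1 = %d presences, n0 = %d absences (prevalence %.3f)\n",
              x$n1, x$n0, x$n1 / (x$n1 + x$n0)))
  if (length(x$variables))
    cat("  variables:", paste(x$variables, collapse = " + "), "\n")
  else cat("  intercept-only model\n")
  cat(sprintf("  AIC %.2f\n", x$aic))
  invisible(x)
}

#' @export
summary.favorability_model <- function(object, ...) {
  structure(list(model = object), class = "summary.favorability_model")
}

#' @export
print.summary.favorability_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nCoefficients:\n")
  print(m$coef_table, digits = 4, row.names = FALSE)
  if (!is.null(m$screening)) {
    cat("\n")
    print(m$screening)
  }
  invisible(x)
}

#' @export
coef.favorability_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict probability or favorability from a fitted model
#'
#' @param object a `favorability_model`.
#' @param newdata a `grid_landscape` or a data.frame holding the model's
#'   variables; `NULL` (default) reuses the training cells.
#' @param type `"favorability"` (default), `"probability"`, or `"link"`
#'   (the linear predictor).  Favorability uses the training prevalence
#'   anchor `n1/n0`.
#' @param ... unused.
#' @return numeric vector, one value per (valid) cell of `newdata`.
#' @export
predict.favorability_model <- function(object, newdata = NULL,
                                       type = c("favorability",
                                                "probability", "link"),
                                       ...) {
  type <- match.arg(type)
  df <- if (is.null(newdata)) object$data
  else if (inherits(newdata, "grid_landscape")) as.data.frame(newdata)
  else as.data.frame(newdata)
  missing <- setdiff(object$variables, names(df))
  if (length(missing))
    stop("newdata lacks model variable(s): ",
         paste(missing, collapse = ", "))
  eta <- rep(object$intercept, nrow(df))
  for (v in object$variables)
    eta <- eta + object$coefficients[[v]] * df[[v]]
  switch(type,
         link = eta,
         probability = stats::plogis(eta),
         favorability = favorability(stats::plogis(eta),
                                     object$n1, object$n0))
}

#' @export
residuals.favorability_model <- function(object,
                                         type = c("deviance", "response"),
                                         ...) {
  type <- match.arg(type)
  y <- object$presence
  mu <- object$fitted_probability
  if (is.null(mu)) mu <- predict(object, type = "probability")
  if (type == "response") return(y - mu)
  d <- -2 * (y * log(pmax(mu, 1e-300)) +
               (1 - y) * log(pmax(1 - mu, 1e-300)))
  sign(y - mu) * sqrt(d)
}

#' Simulate presence/absence data from a fitted model
#'
#' Independent Bernoulli draws per cell from the fitted probabilities —
#' parametric-bootstrap replicates of the species.
#'
#' @param object a `favorability_model` fitted by [favorability_fit()].
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a data.frame with `nsim` 0/1 columns `sim_1`, `sim_2`, ...
#' @export
simulate.favorability_model <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- object$fitted_probability
  if (is.null(mu)) mu <- predict(object, type = "probability")
  draw <- function() stats::rbinom(length(mu), 1L, mu)
  sims <- if (is.null(seed)) replicate(nsim, draw())
  else with_seed(seed, replicate(nsim, draw()))
  out <- as.data.frame(matrix(sims, ncol = nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Map a fitted favorability surface
#'
#' Greyscale image of the favorability (or probability) surface, with
#' optional outline of the high-favorability patch mask.
#'
#' @param x a `favorability_model` from [favorability_fit()].
#' @param what `"favorability"` or `"probability"`.
#' @param patch_threshold draw cells at or above this favorability as the
#'   patch class; `NULL` to skip.
#' @param ... passed to [graphics::image()].
#' @export
plot.favorability_model <- function(x, what = c("favorability",
                                                "probability"),
                                    patch_threshold = 0.8, ...) {
  what <- match.arg(what)
  if (is.null(x$grid))
    stop("model carries no grid; fit it with favorability_fit()")
  vals <- if (what == "favorability") x$favorability
  else x$fitted_probability
  land <- list(n_rows = x$grid$n_rows, n_cols = x$grid$n_cols,
               valid = x$grid$valid)
  class(land) <- "grid_landscape"
  m <- surface_matrix(land, vals)
  # image() draws x along rows; transpose and flip so row 1 is on top
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = z,
                  col = grDevices::gray.colors(64, start = 0, end = 1),
                  xlab = "column", ylab = "row",
                  main = sprintf("%s: %s", x$species_id, what),
                  useRaster = TRUE, zlim = c(0, 1), ...)
  if (!is.null(patch_threshold) && what == "favorability") {
    pm <- !is.na(m) & m >= patch_threshold
    if (any(pm)) {
      idx <- which(pm, arr.ind = TRUE)
      graphics::points(idx[, "col"], nrow(m) - idx[, "row"] + 1,
                       pch = 15, cex = 0.4, col = "white")
    }
  }
  invisible(x)
}
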