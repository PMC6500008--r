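#' Propensity estimation and inverse probability of treatment weighting
#'
#' The exposure (More vs. Less Adherent surveillance) is not randomized:
#' patients at higher perceived risk of recurrence are tested more. The
#' pipeline therefore estimates each patient's propensity of being More
#' Adherent from pre-treatment covariates with gradient-boosted
#' classification trees, and weights patients by the inverse probability of
#' the exposure actually received, targeting the average treatment effect
#' (ATE): w = T/e + (1-T)/(1-e).
#'
#' The number of boosting iterations is not chosen by prediction accuracy
#' but by covariate balance: at a grid of iteration counts the implied
#' weights are formed and the mean absolute standardized mean difference
#' (ASMD) of all covariate indicators — each weighted group mean compared
#' to the unweighted study-population mean, in units of the unweighted
#' population SD — is evaluated; the iteration minimizing mean ASMD wins.
#' Iteration 0 (constant propensity = the treated fraction) is on the grid,
#' so balance-stopping can never do worse than no weighting adjustment.
#' ASMD at or above 0.20 flags imbalance.
#'
#' @name weighting
NULL

#' Expand cohort covariates to a binary indicator matrix
#'
#' One indicator column per category of each categorical covariate
#' (unknown categories are their own indicator), plus the chemotherapy
#' flag and the individual comorbid-condition flags.
#'
#' @param patients Patient table from [simulate_cohort()] (or any table
#'   with the same covariate columns).
#' @param covariates Character vector of categorical covariate columns to
#'   expand; defaults to the full pre-treatment set present in the table.
#' @return Numeric 0/1 matrix, one row per patient, named columns
#'   `covariate.category`.
#' @export
covariate_matrix <- function(patients,
                             covariates = intersect(
                               c("age_group", "race", "sex", "marital",
                                 "dx_year", "buyin", "poverty", "urban",
                                 "region", "stage", "grade", "site"),
                               names(patients))) {
  cols <- list()
  for (v in covariates) {
    f <- factor(patients[[v]])
    mm <- stats::model.matrix(~ f - 1)
    colnames(mm) <- paste(v, levels(f), sep = ".")
    cols[[v]] <- mm
  }
  X <- do.call(cbind, cols)
  if ("chemo" %in% names(patients))
    X <- cbind(X, chemo = as.numeric(patients$chemo))
  flags <- grep("^cm_", names(patients), value = TRUE)
  for (fl in flags) X <- cbind(X, as.numeric(patients[[fl]]))
  colnames(X)[seq(ncol(X) - length(flags) + 1, length.out = length(flags))] <- flags
  storage.mode(X) <- "double"
  X
}

#' ATE inverse probability of treatment weights
#'
#' @param e Propensity of treatment, in (0,1).
#' @param treated 0/1 treatment indicator.
#' @param stabilize Normalize weights to mean 1 within each group
#'   (off by default).
#' @return Numeric weights: `1/e` for treated, `1/(1-e)` for controls.
#' @export
compute_iptw <- function(e, treated, stabilize = FALSE) {
  stopifnot(length(e) == length(treated), all(treated %in% c(0, 1)))
  if (any(e <= 0 | e >= 1)) stop("propensities must lie strictly in (0,1)")
  w <- treated / e + (1 - treated) / (1 - e)
  if (stabilize) {
    for (g in c(0, 1)) {
      idx <- treated == g
      w[idx] <- w[idx] / mean(w[idx])
    }
  }
  w
}

#' Covariate balance vs. the study-population mean
#'
#' For every covariate indicator and each treatment group, the absolute
#' standardized mean difference ASMD = |group mean - population mean| /
#' population SD, where the population mean and SD are always the
#' *unweighted* whole-sample values (the fixed reference), and the group
#' mean is weighted when weights are supplied.
#'
#' @param X Indicator matrix from [covariate_matrix()].
#' @param treated 0/1 indicator.
#' @param weights Optional positive weights; NULL for the unweighted table.
#' @param threshold Imbalance flag threshold (default 0.20).
#' @return Data frame: covariate, asmd_treated, asmd_control, flags.
#' @export
balance_table <- function(X, treated, weights = NULL, threshold = 0.20) {
  stopifnot(nrow(X) == length(treated))
  if (is.null(weights)) weights <- rep(1, nrow(X))
  stopifnot(all(weights > 0), length(weights) == nrow(X))
  m_pop <- colMeans(X)
  s_pop <- apply(X, 2, stats::sd)
  zero_sd <- s_pop == 0
  if (any(zero_sd))
    warning("constant covariate columns, ASMD set to 0: ",
            paste(colnames(X)[zero_sd], collapse = ", "))
  wmean <- function(idx) {
    w <- weights[idx]
    colSums(X[idx, , drop = FALSE] * w) / sum(w)
  }
  asmd <- function(m_g) ifelse(zero_sd, 0, abs(m_g - m_pop) / s_pop)
  a1 <- asmd(wmean(treated == 1))
  a0 <- asmd(wmean(treated == 0))
  data.frame(covariate = colnames(X),
             asmd_treated = unname(a1), asmd_control = unname(a0),
             flag_treated = unname(a1 >= threshold),
             flag_control = unname(a0 >= threshold),
             row.names = NULL)
}

mean_asmd <- function(X, treated, weights) {
  bt <- suppressWarnings(balance_table(X, treated, weights))
  mean(c(bt$asmd_treated, bt$asmd_control))
}

#' Fit a boosted propensity model with balance-driven stopping
#'
#' Gradient-boosted classification trees (logistic loss) on the covariate
#' indicators; the boosting iteration count is selected to minimize the
#' mean ASMD of the implied ATE weights over a grid (every `grid_step`
#' trees up to `max_trees`, plus iteration 0 = constant propensity).
#' Returned propensities are clipped to `[eps, 1 - eps]` so weights stay
#' bounded even under near-perfect separation.
#'
#' @param X Indicator matrix from [covariate_matrix()].
#' @param treated 0/1 treatment indicator.
#' @param max_trees,grid_step,depth,learning_rate,subsample Boosting
#'   hyper-parameters.
#' @param eps Propensity clipping bound.
#' @param seed Seed for the (subsampled) tree fitting.
#' @return List of class `propensity_fit`: `e` (clipped propensities),
#'   `weights`, `best_iteration`, `grid` (iterations and their mean ASMD),
#'   `balance` (weighted balance table at the chosen iteration),
#'   `balance_unweighted`.
#' @export
fit_propensity <- function(X, treated, max_trees = 5000L, grid_step = 100L,
                           depth = 3L, learning_rate = 0.01, subsample = 0.5,
                           eps = 1e-3, seed = 1L) {
  stopifnot(nrow(X) == length(treated), all(treated %in% c(0, 1)))
  if (length(unique(treated)) < 2) stop("both treatment groups must be non-empty")
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (any(!keep)) {
    warning("dropping constant covariate columns: ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }

  dm <- xgboost::xgb.DMatrix(X, label = treated, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = depth,
                  eta = learning_rate, subsample = subsample,
                  tree_method = "hist", nthread = 1, seed = seed),
    data = dm, nrounds = max_trees, verbose = 0)

  clip <- function(e) pmin(pmax(e, eps), 1 - eps)
  grid <- c(0L, seq(grid_step, max_trees, by = grid_step))
  score <- numeric(length(grid))
  e_const <- clip(rep(mean(treated), length(treated)))
  for (j in seq_along(grid)) {
    e_j <- if (grid[j] == 0L) e_const else
      clip(predict(booster, dm, iterationrange = c(1, grid[j])))
    score[j] <- mean_asmd(X, treated, compute_iptw(e_j, treated))
  }
  best <- grid[which.min(score)]
  e <- if (best == 0L) e_const else
    clip(predict(booster, dm, iterationrange = c(1, best)))
  if (any(e <= eps | e >= 1 - eps))
    warning("propensities at the clipping bound; weights truncated")
  w <- compute_iptw(e, treated)
  structure(list(
    e = e, weights = w, best_iteration = best,
    grid = data.frame(iterations = grid, mean_asmd = score),
    balance = balance_table(X, treated, w),
    balance_unweighted = balance_table(X, treated)),
    class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("Boosted propensity fit (balance-stopped)\n")
  cat("  iterations:", x$best_iteration,
      " mean ASMD:", signif(min(x$grid$mean_asmd), 3), "\n")
  cat("  max weighted ASMD:",
      signif(max(x$balance$asmd_treated, x$balance$asmd_control), 3),
      " (flag threshold 0.20)\n")
  invisible(x)
}
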