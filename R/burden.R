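# Case-control burden statistics: 2x2 tables, odds ratios, Woolf intervals.

#' Construct a 2x2 carrier contingency table
#'
#' Cells follow the epidemiological convention: `a` = case carriers, `b` =
#' case non-carriers, `c` = control carriers, `d` = control non-carriers.
#' Non-carrier cells are always derived from totals minus carriers, never
#' taken as input.
#'
#' @param case_carriers,case_n Carrier count and total N in the case panel.
#' @param control_carriers,control_n Same for the control panel.
#' @param labels Character(2): panel labels.
#' @return Object of class `"contingency_2x2"`.
#' @examples
#' contingency_2x2(36, 2366, 16, 22448)
#' @export
contingency_2x2 <- function(case_carriers, case_n, control_carriers,
                            control_n, labels = c("case", "control")) {
  stopifnot(case_carriers >= 0, control_carriers >= 0,
            case_carriers <= case_n, control_carriers <= control_n,
            case_n > 0, control_n > 0)
  structure(list(a = as.numeric(case_carriers),
                 b = as.numeric(case_n - case_carriers),
                 c = as.numeric(control_carriers),
                 d = as.numeric(control_n - control_carriers),
                 labels = labels),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(x$labels, c("carrier", "non-carrier")))
  print(m)
  invisible(x)
}

as_table_cells <- function(t) {
  if (inherits(t, "contingency_2x2")) return(t)
  if (is.numeric(t) && length(t) == 4)
    return(structure(list(a = t[1], b = t[2], c = t[3], d = t[4],
                          labels = c("case", "control")),
                     class = "contingency_2x2"))
  stop("expected a contingency_2x2 or numeric (a, b, c, d)")
}

#' Cross-product odds ratio of a 2x2 table
#'
#' @param t A [contingency_2x2()] or numeric `(a, b, c, d)`.
#' @param correction Apply the Haldane-Anscombe 0.5 correction to every
#'   cell. Off by default.
#' @return The odds ratio `(a*d) / (b*c)`; `Inf`/`NaN` with a warning when a
#'   zero cell makes it undefined and no correction is requested.
#' @examples
#' odds_ratio(contingency_2x2(36, 2366, 16, 22448))   # 21.66...
#' @export
odds_ratio <- function(t, correction = FALSE) {
  t <- as_table_cells(t)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  if (correction) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  if (b == 0 || c == 0) {
    warning("zero cell in b or c: odds ratio undefined/infinite")
  }
  (a * d) / (b * c)
}

#' Woolf (log-normal) confidence interval for a 2x2 odds ratio
#'
#' Computes `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with no
#' continuity correction. The default critical value is the tabulated
#' two-decimal normal quantile for the requested level (1.96 at 95%), the
#' convention under which the reference results were produced; pass
#' `z = qnorm((1 + level) / 2)` for the full-precision quantile.
#'
#' @param t A [contingency_2x2()] or numeric `(a, b, c, d)`.
#' @param level Confidence level, in (0, 1).
#' @param z Normal critical value; default `round(qnorm((1+level)/2), 2)`.
#' @param correction Haldane-Anscombe 0.5 correction (needed when any cell
#'   is zero).
#' @return Named numeric `(low, high)`.
#' @examples
#' woolf_ci(contingency_2x2(36, 2366, 16, 22448))   # c(12.00..., 39.09...)
#' @export
woolf_ci <- function(t, level = 0.95, z = NULL, correction = FALSE) {
  stopifnot(level > 0, level < 1)
  t <- as_table_cells(t)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  if (correction) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  if (min(a, b, c, d) <= 0)
    stop("all four cells must be positive (enable `correction` for zero cells)")
  if (is.null(z)) z <- round(stats::qnorm((1 + level) / 2), 2)
  lor <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(low = exp(lor - z * se), high = exp(lor + z * se))
}

#' Carrier frequency as a percentage
#'
#' @param carriers,n Carrier count and panel size (`n > 0`).
#' @param digits Decimal places for the reported percentage; `NULL` for
#'   full precision.
#' @return `100 * carriers / n`, rounded when `digits` is given.
#' @examples
#' carrier_frequency(36, 2366, digits = 1)    # 1.5
#' carrier_frequency(16, 22448, digits = 2)   # 0.07
#' @export
carrier_frequency <- function(carriers, n, digits = NULL) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(carriers < 0 | carriers > n)) stop("require 0 <= carriers <= n")
  p <- 100 * carriers / n
  if (is.null(digits)) p else round(p, digits)
}

#' Pool control panels assuming no overlap
#'
#' Element-wise sums of panel sizes and carrier counts across control
#' panels. The no-overlap assumption (each individual appears in exactly one
#' panel) is the caller's to assert; it is recorded in the result.
#'
#' @param panels List, each element either `c(n, carriers)` or a manifest
#'   data frame with a logical `carrier` column.
#' @return List with `n`, `carriers`, and `assumption = "no overlap"`.
#' @examples
#' pool_controls(list(c(22448, 16), c(10305, 15), c(5996, 8)))
#' @export
pool_controls <- function(panels) {
  stopifnot(length(panels) >= 1)
  counts <- lapply(panels, function(p) {
    if (is.data.frame(p)) c(nrow(p), sum(p$carrier))
    else { stopifnot(length(p) == 2); as.numeric(p) }
  })
  m <- do.call(rbind, counts)
  list(n = sum(m[, 1]), carriers = sum(m[, 2]), assumption = "no overlap")
}

#' Build a 2x2 table from case and control carrier manifests
#'
#' @param case_manifest,control_manifest Data frames with `sample_id` and a
#'   logical `carrier` column (e.g. from [call_carriers()]).
#' @param labels Panel labels.
#' @return A [contingency_2x2()].
#' @export
build_2x2 <- function(case_manifest, control_manifest,
                      labels = c("case", "control")) {
  if (!nrow(case_manifest) || !nrow(control_manifest))
    stop("empty panel")
  overlap <- intersect(case_manifest$sample_id, control_manifest$sample_id)
  if (length(overlap))
    stop("duplicate sample ids across case and control panels: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  contingency_2x2(sum(case_manifest$carrier), nrow(case_manifest),
                  sum(control_manifest$carrier), nrow(control_manifest),
                  labels = labels)
}

#' Fit a carrier-burden odds-ratio model to a 2x2 case-control table
#'
#' The central fitting function. Estimates the cross-product odds ratio of
#' carrier status between a case panel and a control panel, with a Woolf
#' (log-normal) confidence interval, and returns a model object with the
#' usual accessor methods (`print`, `summary`, `coef`, `confint`, `vcov`,
#' `plot`, `simulate`, `residuals`).
#'
#' @param x A [contingency_2x2()], numeric `(a, b, c, d)` cells, or a
#'   formula `carrier ~ panel` (with `data`).
#' @param ... Passed on to methods.
#' @return Object of class `"ptv_burden"`.
#' @examples
#' fit <- burden_test(contingency_2x2(36, 2366, 16, 22448,
#'                    labels = c("HCM cases", "gnomAD EAS")))
#' fit
#' coef(fit)
#' confint(fit)
#' @export
burden_test <- function(x, ...) UseMethod("burden_test")

#' @rdname burden_test
#' @param level Confidence level for the Woolf interval.
#' @param z Normal critical value; see [woolf_ci()].
#' @param correction Haldane-Anscombe correction, off by default.
#' @param label Comparison label carried into reports and forest tables.
#' @export
burden_test.default <- function(x, level = 0.95, z = NULL,
                                correction = FALSE, label = NULL, ...) {
  tab <- as_table_cells(x)
  if (is.null(z)) z <- round(stats::qnorm((1 + level) / 2), 2)
  or <- odds_ratio(tab, correction = correction)
  ci <- if (min(tab$a, tab$b, tab$c, tab$d) > 0 || correction)
    woolf_ci(tab, level = level, z = z, correction = correction)
  else c(low = NA_real_, high = NA_real_)
  a <- tab$a + if (correction) 0.5 else 0
  b <- tab$b + if (correction) 0.5 else 0
  cc <- tab$c + if (correction) 0.5 else 0
  d <- tab$d + if (correction) 0.5 else 0
  se <- if (min(a, b, cc, d) > 0) sqrt(1/a + 1/b + 1/cc + 1/d) else NA_real_
  structure(list(table = tab,
                 estimate = or, se_log = se, z = z, conf.level = level,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 carrier_freq_case = carrier_frequency(tab$a, tab$a + tab$b),
                 carrier_freq_control = carrier_frequency(tab$c, tab$c + tab$d),
                 correction = correction,
                 label = if (is.null(label)) paste(tab$labels, collapse = " vs ")
                         else label,
                 call = match.call()),
            class = "ptv_burden")
}

#' @rdname burden_test
#' @param data Data frame holding the formula variables: a logical (or
#'   two-level) carrier indicator on the left and a panel factor on the
#'   right.
#' @param case Level of the panel variable identifying cases; defaults to
#'   the first level.
#' @export
burden_test.formula <- function(x, data, case = NULL, ...) {
  mf <- stats::model.frame(x, data)
  carrier <- mf[[1]]
  panel <- as.factor(mf[[2]])
  if (is.factor(carrier)) carrier <- carrier == levels(carrier)[2]
  carrier <- as.logical(carrier)
  if (nlevels(panel) != 2) stop("panel variable must have exactly two levels")
  if (is.null(case)) case <- levels(panel)[1]
  ctrl <- setdiff(levels(panel), case)
  tab <- contingency_2x2(sum(carrier[panel == case]), sum(panel == case),
                         sum(carrier[panel == ctrl]), sum(panel == ctrl),
                         labels = c(case, ctrl))
  fit <- burden_test.default(tab, ...)
  fit$call <- match.call()
  fit
}

#' @export
print.ptv_burden <- function(x, digits = 2, ...) {
  cat("Carrier-burden odds ratio:", x$label, "\n")
  print(x$table)
  cat(sprintf("OR = %.*f, %d%% CI (Woolf): %.*f-%.*f\n", digits, x$estimate,
              round(100 * x$conf.level), digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("carrier frequency: %.2f%% (cases) vs %.2f%% (controls)\n",
              x$carrier_freq_case, x$carrier_freq_control))
  invisible(x)
}

#' @export
summary.ptv_burden <- function(object, ...) {
  z_stat <- log(object$estimate) / object$se_log
  structure(list(fit = object,
                 log_or = log(object$estimate), se = object$se_log,
                 z_stat = z_stat,
                 p_value = 2 * stats::pnorm(-abs(z_stat))),
            class = "summary.ptv_burden")
}

#' @export
print.summary.ptv_burden <- function(x, ...) {
  print(x$fit)
  cat(sprintf("log(OR) = %.4f (SE %.4f), z = %.2f, p = %.3g\n",
              x$log_or, x$se, x$z_stat, x$p_value))
  invisible(x)
}

#' @export
coef.ptv_burden <- function(object, ...) {
  c("log(OR)" = log(object$estimate))
}

#' @export
vcov.ptv_burden <- function(object, ...) {
  matrix(object$se_log^2, 1, 1, dimnames = list("log(OR)", "log(OR)"))
}

#' @export
confint.ptv_burden <- function(object, parm = "OR", level = NULL, ...) {
  if (is.null(level) || level == object$conf.level) {
    ci <- c(object$ci_low, object$ci_high)
  } else {
    ci <- unname(woolf_ci(object$table, level = level,
                          correction = object$correction))
  }
  if (identical(parm, "log(OR)")) ci <- log(ci)
  names(ci) <- c("low", "high")
  ci
}

#' @export
residuals.ptv_burden <- function(object, ...) {
  # Pearson residuals against independence of carrier status and panel
  t <- object$table
  obs <- matrix(c(t$a, t$b, t$c, t$d), 2, 2, byrow = TRUE)
  exp_ <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  r <- (obs - exp_) / sqrt(exp_)
  dimnames(r) <- list(t$labels, c("carrier", "non-carrier"))
  r
}

#' Simulate 2x2 carrier tables from a fitted burden model
#'
#' Draws case and control carrier counts as independent binomials at the
#' fitted per-panel carrier frequencies, holding panel sizes fixed.
#'
#' @param object A `"ptv_burden"` fit.
#' @param nsim Number of tables.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of [contingency_2x2()] tables.
#' @export
simulate.ptv_burden <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  t <- object$table
  n_case <- t$a + t$b; n_ctrl <- t$c + t$d
  p_case <- t$a / n_case; p_ctrl <- t$c / n_ctrl
  a <- stats::rbinom(nsim, n_case, p_case)
  c_ <- stats::rbinom(nsim, n_ctrl, p_ctrl)
  lapply(seq_len(nsim), function(i)
    contingency_2x2(a[i], n_case, c_[i], n_ctrl, labels = t$labels))
}

#' Age- (or otherwise-) restricted re-analysis of a burden comparison
#'
#' Filters both manifests by a predicate, rebuilds the 2x2 table and refits
#' the burden model. The predicate may be a function of the manifest data
#' frame returning a logical vector, or an expression evaluated within it.
#'
#' @param case_manifest,control_manifest Manifests with `sample_id`,
#'   `carrier` and any fields the predicate uses.
#' @param predicate Function `df -> logical`, or a one-sided formula whose
#'   right side is evaluated within each manifest (e.g. `~ age >= 17`).
#' @param ... Passed to [burden_test()].
#' @return A `"ptv_burden"` fit; its `table` holds the filtered cell counts.
#' @export
subgroup_reanalysis <- function(case_manifest, control_manifest, predicate,
                                ...) {
  keep <- function(df) {
    k <- if (is.function(predicate)) predicate(df)
         else eval(predicate[[2]], df, environment(predicate))
    k & !is.na(k)
  }
  cm <- case_manifest[keep(case_manifest), , drop = FALSE]
  ctl <- control_manifest[keep(control_manifest), , drop = FALSE]
  if (!nrow(cm) || !nrow(ctl))
    stop("predicate empties a panel")
  burden_test(build_2x2(cm, ctl), ...)
}
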