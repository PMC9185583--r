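# Per-variable, per-muscle mixed-effects analysis of the exoskeleton effect:
# REML fit of y ~ exo * box + weight + (1 | user), uniformly-weighted
# adjusted means, percent change with delta-method intervals, Holm-adjusted
# families of condition contrasts, and the intra-class correlation used to
# justify the subject random intercept.

#' Build the model frame for one variable and muscle
#'
#' @param features Feature table from [extract_features()] (stacked over
#'   exercises).
#' @param variable Feature column to model (e.g. `"vrms_uV"`).
#' @param muscle Muscle label to subset.
#' @return Data frame with `y` and factors `exo` (levels `noexo`, `exo`),
#'   `box`, `weight`, `user`.
#' @export
make_model_frame <- function(features, variable, muscle = NULL) {
  if (!variable %in% names(features)) {
    abort_input(sprintf("no feature column `%s`", variable))
  }
  sub <- if (is.null(muscle)) features else features[features$muscle == muscle, ]
  if (!nrow(sub)) abort_input("no rows for the requested muscle")
  data.frame(
    y = sub[[variable]],
    exo = factor(sub$condition, levels = c("noexo", "exo")),
    box = factor(sub$box),
    weight = factor(sub$weight_kg),
    user = factor(sub$subject))
}

#' Fit the mixed model for one variable and muscle
#'
#' REML fit of `y ~ exo * box + weight + (1 | user)`: condition, box
#' position, their interaction and box weight as fixed (categorical)
#' effects, and a per-subject random intercept. Terms whose factor has a
#' single level are dropped automatically; if any exo-by-box cell is
#' entirely missing the interaction is dropped with a warning. Missing
#' responses are dropped row-wise.
#'
#' @param frame A [make_model_frame()] data frame.
#' @return An `exo_mixed_fit`: the `lmerMod` in `$model`, the data used,
#'   `$converged`, `$singular`, and the formula.
#' @export
fit_mixed <- function(frame) {
  need <- c("y", "exo", "box", "weight", "user")
  if (!all(need %in% names(frame))) {
    abort_input("frame needs columns y, exo, box, weight, user")
  }
  frame <- droplevels(frame[is.finite(frame$y), , drop = FALSE])
  if (nlevels(frame$user) < 2) {
    abort_input("the per-user random intercept requires at least 2 users")
  }
  if (nlevels(frame$exo) < 2) {
    abort_input("both conditions (exo, noexo) are required")
  }
  terms <- "exo"
  if (nlevels(frame$box) > 1) {
    if (all(table(frame$exo, frame$box) > 0)) {
      terms <- "exo * box"
    } else {
      warning("empty exo-by-box cell: interaction dropped", call. = FALSE)
      terms <- "exo + box"
    }
  }
  if (nlevels(frame$weight) > 1) terms <- paste(terms, "+ weight")
  fml <- as.formula(paste("y ~", terms, "+ (1 | user)"))
  model <- lme4::lmer(fml, data = frame, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
  msgs <- model@optinfo$conv$lme4$messages
  structure(list(model = model, data = frame, formula = fml,
                 converged = is.null(msgs) || !length(msgs),
                 singular = lme4::isSingular(model),
                 messages = msgs),
            class = "exo_mixed_fit")
}

#' @export
print.exo_mixed_fit <- function(x, ...) {
  cat("<exo_mixed_fit> ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  %d rows, %d users; converged: %s; ICC %.3f\n",
              nrow(x$data), nlevels(x$data$user), x$converged, icc(x)))
  invisible(x)
}

#' Intra-class correlation of a mixed fit
#'
#' Fraction of outcome variance attributable to the subject random
#' intercept: `var_user / (var_user + var_residual)`.
#'
#' @param fit An [fit_mixed()] result.
#' @return A fraction in `[0, 1]`; `NA` for a non-converged fit or when both
#'   variance components are zero.
#' @export
icc <- function(fit) {
  if (!inherits(fit, "exo_mixed_fit")) abort_input("`fit` must be an exo_mixed_fit")
  if (!fit$converged) return(NA_real_)
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  vu <- vc$vcov[vc$grp == "user"]
  vr <- vc$vcov[vc$grp == "Residual"]
  if (vu + vr <= 0) return(NA_real_)
  vu / (vu + vr)
}

#' Adjusted (marginal) means of a mixed fit
#'
#' Adjusted means of the requested factors, averaging uniformly over the
#' levels of the other fixed factors, with standard errors from the
#' fixed-effect covariance. `factors = c("exo", "box")` yields the per-box
#' condition curves.
#'
#' @param fit An [fit_mixed()] result.
#' @param factors Character vector of fixed factors to keep.
#' @return Data frame of factor levels, `emmean` and `SE`, with the
#'   mean covariance matrix in attribute `"cov"`.
#' @export
marginal_means <- function(fit, factors = "exo") {
  if (!inherits(fit, "exo_mixed_fit")) abort_input("`fit` must be an exo_mixed_fit")
  # the "involvement in interactions" note is expected: condition means
  # deliberately average over the exo-by-box interaction
  em <- suppressMessages(
    emmeans::emmeans(fit$model, specs = factors, weights = "equal",
                     lmer.df = "asymptotic"))
  s <- as.data.frame(summary(em))
  out <- s[, c(factors, "emmean", "SE")]
  attr(out, "cov") <- em@linfct %*% em@V %*% t(em@linfct)
  out
}

#' Percent change between condition means
#'
#' `(mean_exo - mean_noexo) / mean_noexo * 100`; negative values mean a
#' reduction relative to the no-exoskeleton condition.
#'
#' @param mean_exo,mean_noexo Condition means.
#' @return Percent change; `NA` (with reason) on a zero baseline.
#' @export
percent_change <- function(mean_exo, mean_noexo) {
  if (!is.finite(mean_noexo) || mean_noexo == 0) {
    return(missing_value("zero or missing baseline mean"))
  }
  (mean_exo - mean_noexo) / mean_noexo * 100
}

#' Exoskeleton condition contrast of a mixed fit
#'
#' Marginal condition means, their difference, the asymptotic two-sided
#' p-value, and the percent change with a delta-method confidence
#' half-width on the percent scale.
#'
#' @param fit An [fit_mixed()] result.
#' @param conf_level Confidence level for the half-width.
#' @return One-row data frame: `mean_noexo`, `mean_exo`, `diff`, `se_diff`,
#'   `p`, `percent`, `ci_halfwidth`.
#' @export
exo_effect <- function(fit, conf_level = 0.95) {
  mm <- marginal_means(fit, "exo")
  C <- attr(mm, "cov")
  i_no <- which(mm$exo == "noexo")
  i_ex <- which(mm$exo == "exo")
  m_no <- mm$emmean[i_no]
  m_ex <- mm$emmean[i_ex]
  d <- m_ex - m_no
  se_d <- sqrt(C[i_no, i_no] + C[i_ex, i_ex] - 2 * C[i_no, i_ex])
  p <- 2 * pnorm(-abs(d / se_d))
  pc <- percent_change(m_ex, m_no)
  g <- numeric(2)
  g[i_no] <- -100 * m_ex / m_no^2
  g[i_ex] <- 100 / m_no
  half <- qnorm(1 - (1 - conf_level) / 2) * sqrt(drop(t(g) %*% C %*% g))
  data.frame(mean_noexo = m_no, mean_exo = m_ex, diff = d, se_diff = se_d,
             p = p, percent = as.numeric(pc), ci_halfwidth = half)
}

#' Holm step-down adjustment of a p-value family
#'
#' Step-down Holm adjustment controlling the family-wise error rate: sort
#' ascending, multiply the i-th smallest by `m - i + 1`, enforce monotone
#' non-decreasing adjusted values, cap at 1, restore the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.finite(p) & (p < 0 | p > 1))) {
    abort_input("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "holm")
}

significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", ""), right = TRUE)
}

#' Full per-variable, per-muscle effect analysis
#'
#' Fits the mixed model for every (variable, muscle) pair, extracts the
#' condition contrast and percent change, applies Holm within the chosen
#' family of condition contrasts, and collects the per-box marginal-mean
#' curves and residual diagnostics. Per-fit failures are isolated into
#' flagged rows.
#'
#' @param features Stacked feature table from [extract_features()].
#' @param variables Feature columns to model.
#' @param holm_family `"per_variable"` (adjust across muscles within each
#'   variable, the default) or `"all"` (one family of all contrasts).
#' @param conf_level Confidence level for percent-change half-widths.
#' @return List with `effects` (one row per variable x muscle: percent,
#'   `ci_halfwidth`, `p`, `p_holm`, `stars`, `icc`, convergence flag),
#'   `curves` (per-box adjusted means by condition) and `diagnostics`
#'   (fitted values and residuals per fit).
#' @export
run_effects <- function(features,
                        variables = c("vrms_uV", "tzc_pct", "fmn_hz",
                                      "fmd_hz", "log_fin"),
                        holm_family = c("per_variable", "all"),
                        conf_level = 0.95) {
  holm_family <- match.arg(holm_family)
  muscles <- unique(features$muscle)
  eff <- list()
  curves <- list()
  diags <- list()
  for (v in variables) {
    for (m in muscles) {
      tag <- paste(v, m, sep = ":")
      res <- tryCatch({
        fit <- fit_mixed(make_model_frame(features, v, m))
        e <- exo_effect(fit, conf_level = conf_level)
        mmb <- marginal_means(fit, c("exo", "box"))
        curves[[tag]] <- cbind(variable = v, muscle = m,
                               mmb[, c("exo", "box", "emmean", "SE")])
        diags[[tag]] <- data.frame(
          variable = v, muscle = m,
          fitted = fitted(fit$model),
          residual = residuals(fit$model))
        cbind(variable = v, muscle = m, e,
              icc = icc(fit), converged = fit$converged,
              flag = if (fit$converged) "" else "non_converged")
      }, exolift_error = function(cnd) {
        data.frame(variable = v, muscle = m, mean_noexo = NA, mean_exo = NA,
                   diff = NA, se_diff = NA, p = NA, percent = NA,
                   ci_halfwidth = NA, icc = NA, converged = FALSE,
                   flag = conditionMessage(cnd))
      })
      eff[[tag]] <- res
    }
  }
  effects <- do.call(rbind, eff)
  rownames(effects) <- NULL
  fam <- if (holm_family == "per_variable") effects$variable else
    rep("all", nrow(effects))
  effects$p_holm <- NA_real_
  for (f in unique(fam)) {
    sel <- which(fam == f & is.finite(effects$p))
    effects$p_holm[sel] <- holm_adjust(effects$p[sel])
  }
  effects$stars <- as.character(significance_stars(effects$p_holm))
  list(effects = effects,
       curves = if (length(curves)) do.call(rbind, c(curves,
                                                     make.row.names = FALSE)),
       diagnostics = if (length(diags)) do.call(rbind, c(diags,
                                                         make.row.names = FALSE)),
       holm_family = holm_family)
}
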