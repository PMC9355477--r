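# The statistical workflow: predictor centering, maximal linear mixed model,
# backward elimination (random structure first, then fixed effects), Type II
# Wald chi-square tests, Nakagawa marginal/conditional R-squared, variance
# inflation factors, median split, simple slopes, and SNR-grid contrasts.
#
# Fitting is REML throughout (lme4); fixed-effect p-values are Wald z,
# consistent with chi-square reporting. Random-effect reduction uses REML
# likelihood-ratio tests between models sharing the same fixed structure.

#' Model specification
#'
#' Describes one model of the workflow: the outcome, the fixed terms (built
#' from the centered continuous predictors `block_c`, `rs_c`, `snr_c` and
#' their interactions, written with `:`), and the by-participant random terms
#' (`"intercept"` plus any of the predictors as random slopes).
#'
#' @param outcome `"pupil_baseline_mm"` or `"recall_pct"` (any numeric column
#'   of the model data is accepted).
#' @param fixed character vector of fixed terms. Marginality is enforced: an
#'   interaction requires its constituents.
#' @param random character vector of random terms; must contain
#'   `"intercept"`. Random slopes may outlive their fixed counterparts (a
#'   random Block slope without a fixed Block effect is a legitimate final
#'   model).
#' @return list of class `swir_model_spec`.
#' @export
model_spec <- function(outcome,
                       fixed = c("block_c", "rs_c", "snr_c",
                                 "block_c:rs_c", "block_c:snr_c",
                                 "rs_c:snr_c", "block_c:rs_c:snr_c"),
                       random = c("intercept", "block_c", "rs_c", "snr_c")) {
  if (!"intercept" %in% random)
    stop("random structure must contain the intercept", call. = FALSE)
  for (tm in fixed) {
    parts <- term_components(tm)
    if (length(parts) > 1) {
      for (p in lower_order_terms(tm))
        if (!p %in% fixed)
          stop("marginality violated: `", tm, "` requires `", p, "`",
               call. = FALSE)
    }
  }
  structure(list(outcome = outcome, fixed = fixed, random = random),
            class = "swir_model_spec")
}

#' Maximal model specification
#'
#' The starting point of the workflow: all three centered predictors, every
#' interaction up to the three-way, and by-participant random intercept plus
#' random slopes for all three predictors.
#'
#' @param outcome outcome column name.
#' @return a `swir_model_spec`.
#' @export
maximal_spec <- function(outcome = "pupil_baseline_mm") model_spec(outcome)

term_components <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# all strictly lower-order terms implied by an interaction, in canonical order
lower_order_terms <- function(term) {
  parts <- term_components(term)
  k <- length(parts)
  if (k == 1) return(character(0))
  out <- character(0)
  for (m in seq_len(k - 1)) {
    cmb <- utils::combn(parts, m)
    out <- c(out, apply(cmb, 2, paste, collapse = ":"))
  }
  out
}

# is `a` contained in `b` (proper containment of interaction components)?
term_contained_in <- function(a, b) {
  pa <- term_components(a); pb <- term_components(b)
  length(pa) < length(pb) && all(pa %in% pb)
}

spec_formula <- function(spec) {
  slopes <- setdiff(spec$random, "intercept")
  re <- paste(c("1", slopes), collapse = " + ")
  fx <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  as.formula(paste0(spec$outcome, " ~ ", fx, " + (", re, " | participant)"))
}

#' Center the model predictors
#'
#' Subtracts the grand mean from `block`, `rs_score` and `snr_db`, storing
#' the offsets as an attribute. Following the printed post-hoc arithmetic,
#' predictors are centered but *not* divided by their SD; set
#' `standardize = TRUE` to divide by the SD as well.
#'
#' @param data block-level data frame with columns `block`, and per
#'   participant `rs_score`, `snr_db` (joined from the participant table).
#' @param standardize also divide each predictor by its SD.
#' @return `data` with added columns `block_c`, `rs_c`, `snr_c` and attribute
#'   `"centering"` (a data frame of offsets and scales).
#' @export
center_predictors <- function(data, standardize = FALSE) {
  map <- c(block = "block_c", rs_score = "rs_c", snr_db = "snr_c")
  offs <- data.frame(variable = character(0), center = numeric(0),
                     scale = numeric(0))
  for (raw in names(map)) {
    if (!raw %in% names(data))
      stop("column `", raw, "` not found", call. = FALSE)
    x <- data[[raw]]
    ctr <- mean(x)
    scl <- 1
    xc <- x - ctr
    if (standardize) {
      scl <- sd(x)
      if (scl > 0) xc <- xc / scl
    }
    if (sd(x) == 0)
      warning("predictor `", raw, "` is constant; centered column is all zero")
    data[[map[[raw]]]] <- xc
    offs <- rbind(offs, data.frame(variable = raw, center = ctr, scale = scl))
  }
  attr(data, "centering") <- offs
  data
}

default_lmer_control <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    check.conv.hess = "ignore")
}

#' Fit a linear mixed model of the workflow
#'
#' REML fit of a `swir_model_spec` with an unstructured by-participant
#' random-effects covariance. The fit is flagged singular when any random SD
#' falls below `1e-6` times the outcome SD or any random-effect correlation
#' reaches |0.999|.
#'
#' @param spec a [model_spec()].
#' @param data centered block-level data (see [center_predictors()]) with a
#'   `participant` column.
#' @param reml fit by REML (default) or ML.
#' @param control an [lme4::lmerControl()] object.
#' @return object of class `swir_lmm`: the lme4 fit plus extracted fixed
#'   estimates, Wald 95% CIs, covariance, variance components, and flags.
#' @export
fit_lmm <- function(spec, data, reml = TRUE, control = default_lmer_control()) {
  stopifnot(inherits(spec, "swir_model_spec"))
  if (length(unique(data$participant)) < 2)
    stop("need at least 2 participants", call. = FALSE)
  vars <- unique(unlist(lapply(c(spec$fixed, setdiff(spec$random, "intercept")),
                               term_components)))
  for (v in vars)
    if (anyNA(data[[v]])) stop("missing values in predictor `", v, "`",
                               call. = FALSE)
  fml <- spec_formula(spec)
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = data, REML = reml, control = control),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  se <- sqrt(diag(V))
  vc <- as.data.frame(lme4::VarCorr(fit))
  re_sd <- vc$sdcor[is.na(vc$var2) & vc$grp != "Residual"]
  re_cor <- vc$sdcor[!is.na(vc$var2)]
  ysd <- sd(data[[spec$outcome]])
  singular <- any(re_sd < 1e-6 * ysd) ||
    (length(re_cor) > 0 && any(abs(re_cor) >= 0.999))
  structure(list(
    fit = fit, spec = spec, data = data,
    beta = beta, se = se, vcov = V,
    ci = cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se),
    varcorr = vc, sigma = lme4::getME(fit, "sigma"),
    reml = reml, criterion = as.numeric(logLik(fit)),
    singular = singular, converged = converged,
    n_obs = nrow(data), n_groups = length(unique(data$participant)),
    offsets = attr(data, "centering")
  ), class = "swir_lmm")
}

#' @export
print.swir_lmm <- function(x, ...) {
  cat(sprintf("<swir_lmm: %s ~ %s | random: %s>\n", x$spec$outcome,
              paste(x$spec$fixed, collapse = " + "),
              paste(x$spec$random, collapse = " + ")))
  cat(sprintf("  %d obs, %d participants, %s%s\n", x$n_obs, x$n_groups,
              if (x$reml) "REML" else "ML",
              if (x$singular) ", singular fit" else ""))
  print(round(coef_table(x)[, c("estimate", "ci_lower", "ci_upper", "p")], 4))
  invisible(x)
}

#' Fixed-effect coefficient table
#'
#' @param fit a `swir_lmm`.
#' @return data frame `term`, `estimate`, `se`, `ci_lower`, `ci_upper`, `z`,
#'   `p` (Wald).
#' @export
coef_table <- function(fit) {
  z <- fit$beta / fit$se
  data.frame(term = names(fit$beta), estimate = unname(fit$beta),
             se = unname(fit$se), ci_lower = unname(fit$ci[, "lower"]),
             ci_upper = unname(fit$ci[, "upper"]), z = unname(z),
             p = unname(2 * pnorm(-abs(z))))
}

# Wald p-value of a single fixed term in a fitted model
wald_p <- function(fit, term) {
  ct <- coef_table(fit)
  ct$p[match(term, ct$term)]
}

#' Backward elimination of random then fixed effects
#'
#' Phase 1 prunes the random structure: each random slope is tested by a REML
#' likelihood-ratio test against the model without it (identical fixed
#' structure); the slope with the largest p is dropped while p >=
#' `alpha_random`. While the current fit is singular, the worst slope is
#' dropped regardless of its p, reflecting that a boundary fit already
#' signals an over-parameterized random structure. Phase 2 prunes fixed
#' effects: among terms not contained in any retained interaction, the one
#' with the largest Wald p is dropped while p >= `alpha_fixed`, refitting
#' after each removal. The random intercept and the fixed intercept are never
#' dropped.
#'
#' @param spec starting [model_spec()] (usually [maximal_spec()]).
#' @param data centered model data.
#' @param alpha_random,alpha_fixed retention thresholds.
#' @param control an [lme4::lmerControl()].
#' @return list `fit` (final `swir_lmm`) and `trail` (data frame of every
#'   candidate test and the action taken).
#' @export
backward_eliminate <- function(spec, data, alpha_random = 0.1,
                               alpha_fixed = 0.05,
                               control = default_lmer_control()) {
  trail <- data.frame(phase = character(0), term = character(0),
                      statistic = numeric(0), df = numeric(0),
                      p = numeric(0), dropped = logical(0))
  current <- fit_lmm(spec, data, control = control)

  # Phase 1: random slopes
  repeat {
    slopes <- setdiff(current$spec$random, "intercept")
    if (length(slopes) == 0) break
    q <- length(current$spec$random)
    cand <- lapply(slopes, function(s) {
      sp <- current$spec
      sp$random <- setdiff(sp$random, s)
      fit_lmm(sp, data, control = control)
    })
    stat <- vapply(cand, function(f)
      2 * (current$criterion - f$criterion), numeric(1))
    p <- pchisq(pmax(stat, 0), df = q, lower.tail = FALSE)
    worst <- which.max(p)
    drop_now <- p[worst] >= alpha_random || current$singular
    trail <- rbind(trail, data.frame(
      phase = "random", term = slopes,
      statistic = pmax(stat, 0), df = q, p = p,
      dropped = drop_now & seq_along(slopes) == worst))
    if (!drop_now) break
    current <- cand[[worst]]
  }

  # Phase 2: fixed effects
  repeat {
    fx <- current$spec$fixed
    droppable <- fx[!vapply(fx, function(tm)
      any(vapply(fx, function(o) term_contained_in(tm, o), logical(1))),
      logical(1))]
    if (length(droppable) == 0) break
    p <- vapply(droppable, function(tm) wald_p(current, tm), numeric(1))
    worst <- which.max(p)
    drop_now <- p[worst] >= alpha_fixed
    trail <- rbind(trail, data.frame(
      phase = "fixed", term = droppable,
      statistic = NA_real_, df = 1, p = p,
      dropped = drop_now & seq_along(droppable) == worst))
    if (!drop_now) break
    sp <- current$spec
    sp$fixed <- setdiff(sp$fixed, droppable[worst])
    current <- fit_lmm(sp, data, control = control)
  }
  rownames(trail) <- NULL
  list(fit = current, trail = trail)
}

#' Type II Wald chi-square tests
#'
#' For each fixed term, the Wald chi-square computed with respect for
#' marginality: the term is tested after all other terms except its
#' higher-order relatives (the interactions that contain it). With the
#' full fit's fixed-effect covariance `V`, the statistic is the Wald
#' increment `Q(relatives + term) - Q(relatives)` where
#' `Q(S) = beta_S' V_S^{-1} beta_S` — the construction the standard
#' Type II Wald ANOVA uses. On an orthogonal design this reduces to the
#' marginal (Type III) chi-square of each term.
#'
#' @param fit a `swir_lmm`.
#' @return data frame `term`, `chisq`, `df`, `p`.
#' @export
anova_type2 <- function(fit) {
  fx <- fit$spec$fixed
  if (length(fx) == 0)
    return(data.frame(term = character(0), chisq = numeric(0),
                      df = numeric(0), p = numeric(0)))
  X <- lme4::getME(fit$fit, "X")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    cn <- colnames(X)
    ali <- cn[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient fixed design; aliased: ",
         paste(ali, collapse = ", "), call. = FALSE)
  }
  beta <- fit$beta
  V <- fit$vcov
  wald_q <- function(terms) {
    if (length(terms) == 0) return(0)
    j <- match(terms, names(beta))
    as.numeric(t(beta[j]) %*% solve(V[j, j, drop = FALSE]) %*% beta[j])
  }
  out <- data.frame(term = fx, chisq = NA_real_, df = 1, p = NA_real_)
  for (i in seq_along(fx)) {
    tm <- fx[i]
    relatives <- fx[vapply(fx, function(o) term_contained_in(tm, o),
                           logical(1))]
    chi <- wald_q(c(relatives, tm)) - wald_q(relatives)
    out$chisq[i] <- chi
    out$p[i] <- pchisq(chi, df = 1, lower.tail = FALSE)
  }
  out
}

#' Marginal and conditional R-squared from variance components
#'
#' `marginal = sf / (sf + sr + se)`; `conditional = (sf + sr) / (sf + sr +
#' se)`, where `sf` is the variance of the fixed-effect linear predictor,
#' `sr` the mean random-effect variance contribution, and `se` the residual
#' variance.
#'
#' @param sigma2_f,sigma2_r,sigma2_e variance components.
#' @return named numeric vector `marginal`, `conditional`.
#' @export
r2_from_components <- function(sigma2_f, sigma2_r, sigma2_e) {
  tot <- sigma2_f + sigma2_r + sigma2_e
  c(marginal = sigma2_f / tot, conditional = (sigma2_f + sigma2_r) / tot)
}

#' Nakagawa R-squared of a fitted model
#'
#' Computes the fixed-effect variance as the variance of the fixed linear
#' predictor over the data, the random-effect variance as the mean over
#' observations of the diagonal of the random-design quadratic form
#' `z_i' Sigma z_i`, and combines them with the residual variance via
#' [r2_from_components()].
#'
#' @param fit a `swir_lmm`.
#' @return named numeric vector `marginal`, `conditional`, with the
#'   components as attribute `"components"`.
#' @export
r2_nakagawa <- function(fit) {
  X <- lme4::getME(fit$fit, "X")
  sf <- var(as.numeric(X %*% fit$beta))
  slopes <- setdiff(fit$spec$random, "intercept")
  Zt <- cbind(1, as.matrix(fit$data[, slopes, drop = FALSE]))
  Sig <- re_covariance(fit)
  sr <- mean(rowSums((Zt %*% Sig) * Zt))
  se <- fit$sigma^2
  out <- r2_from_components(sf, sr, se)
  attr(out, "components") <- c(sigma2_f = sf, sigma2_r = sr, sigma2_e = se)
  out
}

# by-participant random-effects covariance matrix in the order
# (intercept, slopes...)
re_covariance <- function(fit) {
  vc <- lme4::VarCorr(fit$fit)[["participant"]]
  m <- as.matrix(vc)
  attr(m, "stddev") <- NULL
  attr(m, "correlation") <- NULL
  m
}

#' Variance inflation factors of the fixed effects
#'
#' `VIF_j = 1 / (1 - R2_j)` with `R2_j` from regressing fixed-design column
#' `j` on the remaining fixed columns (intercept excluded from the set of
#' tested columns). Perfect collinearity yields `Inf`.
#'
#' @param fit a `swir_lmm`, or a numeric design matrix.
#' @return named numeric vector of VIFs.
#' @export
vif_fixed <- function(fit) {
  X <- if (inherits(fit, "swir_lmm")) lme4::getME(fit$fit, "X") else fit
  X <- as.matrix(X)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2)
    stop("need at least 2 fixed-effect columns besides the intercept",
         call. = FALSE)
  out <- setNames(numeric(ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    r2 <- suppressWarnings(
      summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Median split of Reading Span scores
#'
#' Scores strictly above the sample median form the high-WM group; the
#' median and everything below it form the low-WM group, so with an odd
#' number of participants the low group is the larger one.
#'
#' @param rs_scores numeric vector (one per participant).
#' @return factor with levels `"low"`, `"high"`.
#' @export
median_split <- function(rs_scores) {
  if (length(rs_scores) < 2)
    stop("need at least 2 participants", call. = FALSE)
  med <- median(rs_scores)
  if (all(rs_scores == rs_scores[1])) {
    warning("all scores equal; everyone assigned to the low group")
    return(factor(rep("low", length(rs_scores)), levels = c("low", "high")))
  }
  factor(ifelse(rs_scores > med, "high", "low"), levels = c("low", "high"))
}

# group means of centered RS, one value per participant
group_rs_means <- function(fit, groups = NULL) {
  d <- fit$data
  pid <- unique(d$participant)
  rs_c <- d$rs_c[match(pid, d$participant)]
  if (is.null(groups)) groups <- median_split(rs_c)
  stopifnot(length(groups) == length(pid))
  c(low = mean(rs_c[groups == "low"]), high = mean(rs_c[groups == "high"]))
}

coef_or_zero <- function(fit, term) {
  if (term %in% names(fit$beta)) unname(fit$beta[term]) else 0
}

# delta-method SE of c'beta using only the named coefficients present
contrast_se <- function(fit, weights) {
  keep <- intersect(names(weights), names(fit$beta))
  if (length(keep) == 0) return(0)
  w <- weights[keep]
  sqrt(as.numeric(t(w) %*% fit$vcov[keep, keep, drop = FALSE] %*% w))
}

#' Simple slopes of SNR by working-memory group
#'
#' Splits participants on the median of the centered Reading Span score and
#' evaluates the conditional SNR slope at each group's mean centered RS:
#' `slope_g = b_snr + b_rs_snr * m_g`, with delta-method standard errors from
#' the fixed-effect covariance, and a Wald test of the slope difference
#' `b_rs_snr * (m_high - m_low)`. Without an interaction term both slopes
#' equal `b_snr`.
#'
#' @param fit a `swir_lmm` containing an SNR term.
#' @param groups optional factor (`low`/`high`, one per participant, in the
#'   order of `unique(fit$data$participant)`); defaults to the median split.
#' @return list of class `swir_posthoc_slopes`: `slopes` data frame (group,
#'   `m_rs_c`, `slope`, `se`, `ci_lower`, `ci_upper`) and `difference`
#'   (estimate, se, z, p).
#' @export
simple_slopes <- function(fit, groups = NULL) {
  m <- group_rs_means(fit, groups)
  b_snr <- coef_or_zero(fit, "snr_c")
  b_int <- coef_or_zero(fit, "rs_c:snr_c")
  rows <- lapply(names(m), function(g) {
    w <- c("snr_c" = 1, "rs_c:snr_c" = m[[g]])
    se <- contrast_se(fit, w)
    data.frame(group = g, m_rs_c = m[[g]], slope = b_snr + b_int * m[[g]],
               se = se)
  })
  slopes <- do.call(rbind, rows)
  slopes$ci_lower <- slopes$slope - 1.96 * slopes$se
  slopes$ci_upper <- slopes$slope + 1.96 * slopes$se
  dm <- m[["high"]] - m[["low"]]
  dw <- c("rs_c:snr_c" = dm)
  dse <- contrast_se(fit, dw)
  dest <- b_int * dm
  z <- if (dse > 0) dest / dse else 0
  structure(list(slopes = slopes,
                 difference = list(estimate = dest, se = dse, z = z,
                                   p = if (dse > 0) 2 * pnorm(-abs(z)) else 1)),
            class = "swir_posthoc_slopes")
}

#' @export
print.swir_posthoc_slopes <- function(x, ...) {
  cat("Simple slopes of centered SNR by WM group:\n")
  print(transform(x$slopes, slope = round(slope, 4), se = round(se, 4),
                  ci_lower = round(ci_lower, 4),
                  ci_upper = round(ci_upper, 4),
                  m_rs_c = round(m_rs_c, 3)))
  cat(sprintf("difference (high - low): %.4f, z = %.2f, p = %.4f\n",
              x$difference$estimate, x$difference$z, x$difference$p))
  invisible(x)
}

#' Group contrasts across a grid of centered SNR values
#'
#' At each centered SNR value `s` the predicted high-minus-low group
#' difference in the outcome is `(b_rs + b_rs_snr * s) * (m_high - m_low)`,
#' tested per point with an unadjusted Wald z (only two groups are compared
#' at each point).
#'
#' @param fit a `swir_lmm`.
#' @param groups optional group factor (see [simple_slopes()]).
#' @param grid centered SNR values, default `-5..7` in steps of 1.
#' @return data frame `snr_c`, `difference`, `se`, `z`, `p`, `significant`.
#' @export
snr_grid_contrasts <- function(fit, groups = NULL, grid = -5:7) {
  m <- group_rs_means(fit, groups)
  dm <- m[["high"]] - m[["low"]]
  b_rs <- coef_or_zero(fit, "rs_c")
  b_int <- coef_or_zero(fit, "rs_c:snr_c")
  out <- data.frame(snr_c = grid)
  out$difference <- (b_rs + b_int * grid) * dm
  out$se <- vapply(grid, function(s)
    contrast_se(fit, c("rs_c" = dm, "rs_c:snr_c" = s * dm)), numeric(1))
  out$z <- ifelse(out$se > 0, out$difference / out$se, 0)
  out$p <- ifelse(out$se > 0, 2 * pnorm(-abs(out$z)), 1)
  out$significant <- out$p < 0.05
  out
}

#' Run the full modelling workflow on a block table
#'
#' Joins participant covariates onto the block table, centers the predictors,
#' runs backward elimination from the maximal model, and computes the Type II
#' ANOVA, R-squared, VIFs and (for the pupil model, when the interaction
#' survived) the post-hoc simple slopes and grid contrasts.
#'
#' @param blocks block table (see [read_block_table()]).
#' @param participants participant table (see [read_participants()]).
#' @param outcome `"pupil_baseline_mm"` or `"recall_pct"`.
#' @param cfg a [pipeline_config()] supplying the elimination alphas.
#' @return list `fit`, `trail`, `anova`, `r2`, `vif`, `slopes`, `grid`.
#' @export
analyze_blocks <- function(blocks, participants,
                           outcome = c("pupil_baseline_mm", "recall_pct"),
                           cfg = pipeline_config()) {
  outcome <- match.arg(outcome)
  keep <- participants$included &
    !is.na(participants$rs_score) & !is.na(participants$snr_db)
  participants <- participants[keep, , drop = FALSE]
  d <- merge(blocks, participants[, c("id", "rs_score", "snr_db")],
             by.x = "participant", by.y = "id")
  d <- d[!is.na(d[[outcome]]), , drop = FALSE]
  d <- center_predictors(d)
  be <- backward_eliminate(maximal_spec(outcome), d,
                           alpha_random = cfg$alpha_random,
                           alpha_fixed = cfg$alpha_fixed)
  fit <- be$fit
  res <- list(fit = fit, trail = be$trail, anova = anova_type2(fit),
              r2 = r2_nakagawa(fit),
              vif = tryCatch(vif_fixed(fit), error = function(e) NULL),
              slopes = NULL, grid = NULL)
  if (all(c("snr_c", "rs_c:snr_c") %in% fit$spec$fixed)) {
    res$slopes <- simple_slopes(fit)
    res$grid <- snr_grid_contrasts(fit)
  }
  res
}
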