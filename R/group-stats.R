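#' Normality gate for choosing the downstream test family
#'
#' Lilliefors test (Kolmogorov-Smirnov with estimated mean and SD) at the
#' given alpha; "normal" routes to t / GLM tests, "non-normal" to rank
#' tests. A constant vector is classified non-normal with a warning.
#'
#' @param values numeric vector, length >= 5.
#' @param alpha significance level (default 0.05).
#' @return `"normal"` or `"non-normal"`, with the Lilliefors p-value in
#'   attribute `p`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("normality gate needs at least 5 observations")
  if (sd(values) == 0) {
    warning("constant input; classifying as non-normal")
    return(structure("non-normal", p = NA_real_))
  }
  p <- nortest::lillie.test(values)$p.value
  structure(if (p >= alpha) "normal" else "non-normal", p = p)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjustment of a vector of p-values; rejections at level `q` are
#' the tests with adjusted p <= q.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` p-values and logical `reject` mask.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  adjusted <- p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

# design matrix [intercept, group(patient=1), centered covariates]; covariate
# columns without variation are dropped so the model stays full-rank
build_design <- function(group, covariates = NULL) {
  g <- as.integer(group == "patient")
  x <- cbind(intercept = 1, group = g)
  if (!is.null(covariates) && ncol(covariates) > 0) {
    for (nm in colnames(covariates)) {
      col <- covariates[[nm]]
      if (is.character(col) || is.factor(col)) {
        col <- as.integer(factor(col)) - 1
      }
      if (sd(col) > 0) {
        x <- cbind(x, scale(col, scale = FALSE)[, 1])
        colnames(x)[ncol(x)] <- nm
      }
    }
  }
  x
}

# vectorized least squares of many responses on one design; per-response
# group-coefficient estimate, t statistic and two-sided p-value
glm_group_scan <- function(y, design) {
  n <- nrow(y)
  rank <- qr(design)$rank
  if (rank < ncol(design)) stop("singular covariate design")
  xtx_inv <- solve(crossprod(design))
  beta <- xtx_inv %*% crossprod(design, y)
  res <- y - design %*% beta
  df <- n - ncol(design)
  if (df < 1) stop("not enough observations for the design")
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * xtx_inv["group", "group"])
  tstat <- beta["group", ] / se
  p <- 2 * pt(-abs(tstat), df)
  list(beta = beta["group", ], t = tstat, p = p, df = df)
}

#' Edgewise group comparison of participant-specific state FC
#'
#' Per edge, a univariate linear model `FC ~ group + age + sex` is fitted
#' over the participants in whom the state occurs; the group coefficient's t
#' statistic and two-sided p-value are reported and FDR-corrected over all
#' edges of the state. With no covariate variation the model reduces to the
#' pooled-variance two-sample t-test. A state with fewer than 2 participants
#' per group is skipped with a warning (as happens for rare states).
#'
#' @param sfc_list list of `participant_state_fc`, one per participant.
#' @param manifest data frame with columns `id`, `group` and the covariates.
#' @param state state index.
#' @param q FDR level (default 0.05).
#' @param covariates covariate column names in `manifest`
#'   (default `c("age", "sex")`).
#' @return data frame with columns `i`, `j`, `region_i`, `region_j`, `beta`,
#'   `t`, `p`, `p_fdr`, `direction`, `significant`, plus attributes `state`,
#'   `n_control`, `n_patient`; or NULL when the state is skipped.
#' @export
edgewise_glm <- function(sfc_list, manifest, state, q = 0.05,
                         covariates = c("age", "sex")) {
  ids <- vapply(sfc_list, `[[`, "", "id")
  present <- vapply(sfc_list, function(s) s$counts[state] > 0, logical(1))
  rows <- match(ids[present], manifest$id)
  grp <- manifest$group[rows]
  if (sum(grp == "control") < 2 || sum(grp == "patient") < 2) {
    warning("state ", state, " skipped: fewer than 2 participants per group")
    return(NULL)
  }
  y <- do.call(rbind, lapply(sfc_list[present], function(s) {
    s$edge_medians[[state]]
  }))
  design <- build_design(grp, manifest[rows, covariates, drop = FALSE])
  fit <- glm_group_scan(y, design)
  fdr <- bh_fdr(fit$p, q)

  p_reg <- (1 + sqrt(1 + 8 * ncol(y))) / 2
  pairs <- edge_pairs(round(p_reg))
  labels <- sfc_list[[which(present)[1]]]$matrices[[state]]
  region_names <- rownames(labels)
  out <- data.frame(
    i = pairs$i, j = pairs$j,
    region_i = region_names[pairs$i], region_j = region_names[pairs$j],
    beta = fit$beta, t = fit$t, p = fit$p, p_fdr = fdr$adjusted,
    direction = ifelse(fit$beta > 0, "patient>control", "patient<control"),
    significant = fdr$reject,
    stringsAsFactors = FALSE)
  attr(out, "state") <- state
  attr(out, "n_control") <- sum(grp == "control")
  attr(out, "n_patient") <- sum(grp == "patient")
  attr(out, "df") <- fit$df
  out
}

#' Regionwise group comparison of temporal variability
#'
#' Same covariate-adjusted linear model as [edgewise_glm()], applied to each
#' region's temporal variability, with FDR correction over the regions.
#' Regions invalid for any participant are dropped with a note.
#'
#' @param profiles list of `variability_profile`.
#' @param manifest data frame with `id`, `group` and covariates.
#' @param q FDR level.
#' @param covariates covariate column names.
#' @return data frame with columns `region`, `beta`, `t`, `p`, `p_fdr`,
#'   `direction`, `significant`.
#' @export
variability_glm <- function(profiles, manifest, q = 0.05,
                            covariates = c("age", "sex")) {
  ids <- vapply(profiles, `[[`, "", "id")
  y <- do.call(rbind, lapply(profiles, `[[`, "v"))
  ok <- colSums(is.na(y)) == 0
  if (!all(ok)) {
    message(sum(!ok), " region(s) dropped from variability stats (invalid)")
  }
  y <- y[, ok, drop = FALSE]
  rows <- match(ids, manifest$id)
  design <- build_design(manifest$group[rows],
                         manifest[rows, covariates, drop = FALSE])
  fit <- glm_group_scan(y, design)
  fdr <- bh_fdr(fit$p, q)
  data.frame(region = colnames(y), beta = fit$beta, t = fit$t, p = fit$p,
             p_fdr = fdr$adjusted,
             direction = ifelse(fit$beta > 0, "patient>control",
                                "patient<control"),
             significant = fdr$reject, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted Mann-Whitney U test
#'
#' Values are residualized on the covariates by ordinary least squares with
#' both groups pooled (no group term), then a two-sided Mann-Whitney U test
#' compares the residuals between groups. With no covariates this reduces to
#' the plain U test. The U statistic is reported in the min convention.
#'
#' @param values numeric vector.
#' @param group character/factor with levels including "patient" and
#'   "control" (any two groups work).
#' @param covariates optional data frame of covariates (same length).
#' @return list with `U`, `p`, `method`.
#' @export
adjusted_rank_test <- function(values, group, covariates = NULL) {
  group <- as.character(group)
  gs <- sort(unique(group))
  if (length(gs) != 2) stop("exactly two groups required")
  if (min(table(group)) < 2) stop("need at least 2 observations per group")
  if (!is.null(covariates) && ncol(covariates) > 0) {
    df <- data.frame(.y = values, covariates)
    fit <- lm(.y ~ ., data = df)
    if (fit$rank < ncol(model.matrix(fit))) stop("singular covariate design")
    r <- resid(fit)
  } else {
    r <- values
  }
  wt <- suppressWarnings(wilcox.test(r[group == gs[1]], r[group == gs[2]],
                                     exact = NULL))
  w <- unname(wt$statistic)
  n1 <- sum(group == gs[1])
  n2 <- sum(group == gs[2])
  list(U = min(w, n1 * n2 - w), p = wt$p.value,
       method = if (is.null(covariates)) "Mann-Whitney U" else
         "Mann-Whitney U on OLS residuals")
}

#' Area under the ROC curve by the rank formulation
#'
#' AUC equals the probability that a random positive (patient) scores above
#' a random negative (control), with 0.5 credit for ties (the Mann-Whitney
#' statistic divided by n1*n0). Orientation is chosen so the reported AUC is
#' >= 0.5 and recorded in the `orientation` attribute.
#'
#' @param scores numeric scores.
#' @param labels group labels; `positive` marks the positive class.
#' @param positive label of the positive class (default "patient").
#' @return AUC in \[0.5, 1\] with attributes `orientation`
#'   (`"positive>negative"` or `"positive<negative"`) and `auc_raw`.
#' @export
roc_auc <- function(scores, labels, positive = "patient") {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  r <- rank(scores)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (auc >= 0.5) {
    structure(auc, orientation = "positive>negative", auc_raw = auc)
  } else {
    structure(1 - auc, orientation = "positive<negative", auc_raw = auc)
  }
}

#' Median strength of significant FC per participant
#'
#' For each participant in whom the state occurs, the median of their
#' state-specific FC values over the significant edges of one direction.
#'
#' @param sfc_list list of `participant_state_fc`.
#' @param edges data frame with columns `i`, `j` (as from [edgewise_glm()]),
#'   already filtered to the edge set of interest.
#' @param state state index.
#' @return named numeric vector (participants with the state absent are
#'   excluded).
#' @export
median_significant_strength <- function(sfc_list, edges, state) {
  if (nrow(edges) == 0) {
    stop("empty significant edge set for state ", state)
  }
  present <- vapply(sfc_list, function(s) s$counts[state] > 0, logical(1))
  p <- nrow(sfc_list[[which(present)[1]]]$matrices[[state]])
  idx <- edge_index(edges$i, edges$j, p)
  out <- vapply(sfc_list[present], function(s) {
    median(s$edge_medians[[state]][idx])
  }, numeric(1))
  setNames(out, vapply(sfc_list[present], `[[`, "", "id"))
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after ordinary least
#' squares on the covariates; the two-sided p-value uses a t distribution
#' with `n - 2 - n_covariates` degrees of freedom. With no covariates this is
#' the plain Pearson correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data frame of controlled variables.
#' @return list with `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    keep <- complete.cases(x, y)
    ncov <- 0
    rx <- x[keep]
    ry <- y[keep]
  } else {
    covariates <- as.data.frame(covariates)
    keep <- complete.cases(x, y, covariates)
    ncov <- ncol(covariates)
    cc <- covariates[keep, , drop = FALSE]
    fx <- lm(x[keep] ~ ., data = cc)
    fy <- lm(y[keep] ~ ., data = cc)
    if (fx$rank < ncol(model.matrix(fx))) stop("singular covariate design")
    rx <- resid(fx)
    ry <- resid(fy)
  }
  n <- sum(keep)
  if (n < ncov + 3) stop("need at least n_covariates + 3 complete cases")
  r <- cor(rx, ry)
  df <- n - 2 - ncov
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  list(r = r, p = p, n = n, df = df)
}

#' Demographics and clinical table with between-group tests
#'
#' Group means and SDs with the conventional test per variable: two-sample
#' t-test for age and MMSE, Mann-Whitney U for NPI, chi-square (without
#' continuity correction) for sex. Missing values are dropped per variable
#' and counted.
#'
#' @param manifest data frame with `id`, `group`, `age`, `sex`, `MMSE`,
#'   `NPI`.
#' @param welch use the Welch (unequal-variance) t statistic (default TRUE).
#' @return data frame, one row per variable: group summaries, test, p-value,
#'   missing count.
#' @export
demographics_table <- function(manifest, welch = TRUE) {
  for (g in c("control", "patient")) {
    if (!any(manifest$group == g)) stop("group ", g, " is empty")
  }
  rows <- list()
  summarize_num <- function(var, test_name) {
    v <- manifest[[var]]
    keep <- !is.na(v)
    vc <- v[keep & manifest$group == "control"]
    vp <- v[keep & manifest$group == "patient"]
    p <- if (test_name == "t") {
      if (sd(vc) == 0 && sd(vp) == 0) {
        # degenerate: no within-group variation, so the t statistic is
        # undefined; report the limit case
        if (mean(vc) == mean(vp)) 1 else 0
      } else {
        t.test(vp, vc, var.equal = !welch)$p.value
      }
    } else {
      suppressWarnings(wilcox.test(vp, vc)$p.value)
    }
    data.frame(variable = var,
               control = sprintf("%.2f (%.2f)", mean(vc), sd(vc)),
               patient = sprintf("%.2f (%.2f)", mean(vp), sd(vp)),
               test = if (test_name == "t") "two-sample t" else
                 "Mann-Whitney U",
               p = p, n_missing = sum(!keep), stringsAsFactors = FALSE)
  }
  rows$age <- summarize_num("age", "t")
  if ("MMSE" %in% names(manifest)) rows$MMSE <- summarize_num("MMSE", "t")
  if ("NPI" %in% names(manifest)) rows$NPI <- summarize_num("NPI", "U")
  if ("sex" %in% names(manifest)) {
    tab <- table(manifest$group, manifest$sex)
    p_sex <- if (all(tab > 0) && ncol(tab) > 1) {
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    } else {
      1
    }
    counts <- function(g) paste(sprintf("%d %s", tab[g, ], colnames(tab)),
                                collapse = ", ")
    rows$sex <- data.frame(variable = "sex", control = counts("control"),
                           patient = counts("patient"), test = "chi-square",
                           p = p_sex, n_missing = sum(is.na(manifest$sex)),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
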