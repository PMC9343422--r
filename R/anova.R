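#' Bonferroni adjustment
#'
#' Multiplies each p-value by the comparison count and caps at 1.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param m number of comparisons in the family (default `length(pvalues)`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(pvalues, m = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1)) stop("bonferroni: p-values must lie in [0, 1]")
  if (m < 1) stop("bonferroni: m must be >= 1")
  pmin(1, pvalues * m)
}

#' Two-way repeated-measures ANOVA with Bonferroni post hocs
#'
#' Fully within-subject two-factor ANOVA for a balanced design: every
#' subject observed once in every condition x sensor-pair cell. Sums of
#' squares are computed from cell means (classical balanced decomposition)
#' and, under the default `error_term = "within"`, each effect is tested
#' against its own interaction with subjects:
#' condition `F(a-1, (s-1)(a-1))`, pair `F(b-1, (s-1)(b-1))`, interaction
#' `F((a-1)(b-1), (s-1)(a-1)(b-1))`. With `error_term = "pooled"` the three
#' subject-interaction terms are pooled into one error mean square. No
#' sphericity correction is applied.
#'
#' Post hoc comparisons are paired t-tests, Bonferroni-corrected within
#' their own family: the conditions compared on subject condition-means, and
#' all pairwise contrasts of the sensor pairs on subject pair-means.
#'
#' @param data data frame with columns `subject`, `condition`, `pair`,
#'   `value` (one metric, one direction). `pair` may be any label, e.g.
#'   `"9-10"`.
#' @param error_term `"within"` (default) or `"pooled"`.
#' @param sphericity `"none"` (default) or `"greenhouse-geisser"`: with the
#'   latter, each within effect's degrees of freedom are multiplied by the
#'   Box/Greenhouse-Geisser epsilon estimated from the subject-level
#'   covariance of orthonormal contrasts (only meaningful with
#'   `error_term = "within"`; F statistics are unchanged, p-values
#'   recomputed).
#' @param posthoc logical; compute post hoc tables (default `TRUE`).
#' @param alpha significance level recorded in the result (default 0.05).
#' @return An object of class `sway_anova`: list with `anova` (data frame of
#'   effects: `effect`, `df1`, `df2`, `F`, `p`), `post_hoc_condition`,
#'   `post_hoc_pair` (data frames with `comparison`, `t`, `df`, `p_adj`),
#'   and `ss` (the full sum-of-squares decomposition).
#' @export
two_way_rm_anova <- function(data, error_term = c("within", "pooled"),
                             sphericity = c("none", "greenhouse-geisser"),
                             posthoc = TRUE, alpha = 0.05) {
  error_term <- match.arg(error_term)
  sphericity <- match.arg(sphericity)
  need <- c("subject", "condition", "pair", "value")
  if (!all(need %in% names(data)))
    stop("two_way_rm_anova: data must have columns subject, condition, pair, value")
  data$subject <- factor(data$subject)
  data$condition <- factor(data$condition)
  data$pair <- factor(data$pair, levels = unique(data$pair))
  s <- nlevels(data$subject); a <- nlevels(data$condition); b <- nlevels(data$pair)
  if (s < 3) stop("two_way_rm_anova: need at least 3 subjects")
  tab <- table(data$subject, data$condition, data$pair)
  if (any(tab != 1)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    msg <- if (nrow(miss) > 0)
      paste(apply(miss, 1, function(r)
        sprintf("(%s, %s, %s)", dimnames(tab)[[1]][r[1]],
                dimnames(tab)[[2]][r[2]], dimnames(tab)[[3]][r[3]])),
        collapse = ", ")
    else "duplicated cells present"
    stop("two_way_rm_anova: design not balanced; problem cells: ", msg)
  }

  y <- data$value
  gm <- mean(y)
  m_s <- tapply(y, data$subject, mean)
  m_a <- tapply(y, data$condition, mean)
  m_b <- tapply(y, data$pair, mean)
  m_ab <- tapply(y, list(data$condition, data$pair), mean)
  m_sa <- tapply(y, list(data$subject, data$condition), mean)
  m_sb <- tapply(y, list(data$subject, data$pair), mean)

  ss_a <- s * b * sum((m_a - gm)^2)
  ss_b <- s * a * sum((m_b - gm)^2)
  ss_ab <- s * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + gm)^2)
  ss_s <- a * b * sum((m_s - gm)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, s), m_a) + gm)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, s), m_b) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_sa - ss_sb

  df <- list(a = a - 1, b = b - 1, ab = (a - 1) * (b - 1),
             sa = (s - 1) * (a - 1), sb = (s - 1) * (b - 1),
             sab = (s - 1) * (a - 1) * (b - 1))
  if (ss_sa <= 0 && ss_sb <= 0 && ss_sab <= 0)
    stop("two_way_rm_anova: zero within-cell variance; F undefined")

  eff <- function(ss_eff, df_eff, ss_err, df_err) {
    Fv <- (ss_eff / df_eff) / (ss_err / df_err)
    c(df1 = df_eff, df2 = df_err, F = Fv,
      p = stats::pf(Fv, df_eff, df_err, lower.tail = FALSE))
  }
  if (error_term == "within") {
    rows <- rbind(condition = eff(ss_a, df$a, ss_sa, df$sa),
                  pair = eff(ss_b, df$b, ss_sb, df$sb),
                  interaction = eff(ss_ab, df$ab, ss_sab, df$sab))
  } else {
    ss_err <- ss_sa + ss_sb + ss_sab
    df_err <- df$sa + df$sb + df$sab
    rows <- rbind(condition = eff(ss_a, df$a, ss_err, df_err),
                  pair = eff(ss_b, df$b, ss_err, df_err),
                  interaction = eff(ss_ab, df$ab, ss_err, df_err))
  }
  anova_tab <- data.frame(effect = rownames(rows), rows, row.names = NULL)

  if (sphericity == "greenhouse-geisser" && error_term == "within") {
    # Box epsilon from orthonormal contrasts of the subject-level responses
    orth <- function(k) {
      C <- stats::contr.helmert(k)
      qr.Q(qr(C))[, seq_len(k - 1), drop = FALSE] |> t()
    }
    cells <- tapply(y, list(data$subject, data$condition, data$pair), mean)
    M_sab <- matrix(cells, nrow = s)           # s x (a*b), b varying slowest
    eps <- c(condition = 1,                    # two levels are always spherical
             pair = gg_epsilon(m_sb, orth(b)),
             interaction = gg_epsilon(M_sab,
                                      kronecker(orth(b), orth(a))))
    anova_tab$epsilon <- unname(eps)
    anova_tab$df1 <- anova_tab$df1 * anova_tab$epsilon
    anova_tab$df2 <- anova_tab$df2 * anova_tab$epsilon
    anova_tab$p <- stats::pf(anova_tab$F, anova_tab$df1, anova_tab$df2,
                             lower.tail = FALSE)
  }

  res <- list(anova = anova_tab, alpha = alpha, error_term = error_term,
              ss = list(condition = ss_a, pair = ss_b, interaction = ss_ab,
                        subject = ss_s, subject_condition = ss_sa,
                        subject_pair = ss_sb,
                        subject_condition_pair = ss_sab, total = ss_tot))

  if (posthoc) {
    paired_t <- function(x1, x2) {
      d <- x1 - x2
      t_ <- mean(d) / (stats::sd(d) / sqrt(length(d)))
      c(t = t_, df = length(d) - 1,
        p = 2 * stats::pt(abs(t_), length(d) - 1, lower.tail = FALSE))
    }
    # conditions on subject condition-means
    cond_lv <- levels(data$condition)
    ph_c <- NULL
    cmb <- utils::combn(length(cond_lv), 2)
    pc <- apply(cmb, 2, function(ix) paired_t(m_sa[, ix[1]], m_sa[, ix[2]]))
    ph_c <- data.frame(comparison = apply(cmb, 2, function(ix)
      paste(cond_lv[ix], collapse = " vs ")),
      t = pc["t", ], df = pc["df", ],
      p_adj = bonferroni(pc["p", ], ncol(cmb)))
    # sensor pairs on subject pair-means
    pair_lv <- levels(data$pair)
    cmb2 <- utils::combn(length(pair_lv), 2)
    pp <- apply(cmb2, 2, function(ix) paired_t(m_sb[, ix[1]], m_sb[, ix[2]]))
    ph_p <- data.frame(comparison = apply(cmb2, 2, function(ix)
      paste(pair_lv[ix], collapse = " vs ")),
      t = pp["t", ], df = pp["df", ],
      p_adj = bonferroni(pp["p", ], ncol(cmb2)))
    res$post_hoc_condition <- ph_c
    res$post_hoc_pair <- ph_p
  }
  structure(res, class = "sway_anova")
}

# Box / Greenhouse-Geisser epsilon: M is the subject-by-level matrix, C an
# orthonormal contrast basis for the effect.
gg_epsilon <- function(M, C) {
  S <- stats::cov(M)
  A <- C %*% S %*% t(C)
  sum(diag(A))^2 / (nrow(A) * sum(A * A))
}

#' @export
print.sway_anova <- function(x, ...) {
  cat(sprintf("<sway_anova> error term: %s\n", x$error_term))
  print(format(x$anova, digits = 4))
  if (!is.null(x$post_hoc_pair)) {
    sig <- x$post_hoc_pair[x$post_hoc_pair$p_adj < x$alpha, ]
    cat(sprintf("significant pair post hocs (p_adj < %g): %d of %d\n",
                x$alpha, nrow(sig), nrow(x$post_hoc_pair)))
    if (nrow(sig) > 0 && nrow(sig) <= 20) print(format(sig, digits = 3))
  }
  invisible(x)
}
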