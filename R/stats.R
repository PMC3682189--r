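#' One-sample t-test of decoding accuracies against chance
#'
#' Upper-tailed one-sample t-test of a vector of per-subject accuracies
#' against the chance level, which for three classes is exactly 1/3 (the
#' commonly printed "33\%" is presentation rounding).
#' \eqn{t = (\bar x - \mu_0) / (s / \sqrt n)}, df = n - 1, upper-tail p.
#'
#' @param accuracies numeric vector, length >= 2, nonzero variance.
#' @param chance chance level (default 1/3).
#' @return a \code{mvpa_test} list: statistic, df, p, tail.
#' @export
t_vs_chance <- function(accuracies, chance = 1/3) {
  n <- length(accuracies)
  if (n < 2) stop("need at least 2 accuracies")
  s <- sd(accuracies)
  if (s == 0) stop("zero variance in accuracies")
  t <- (mean(accuracies) - chance) / (s / sqrt(n))
  mvpa_test(t, n - 1, pt(t, n - 1, lower.tail = FALSE), "one",
            "one-sample t vs chance")
}

#' Paired t-test between two within-subject conditions
#'
#' Two-tailed paired t-test on the element-wise differences.
#'
#' @param a,b equal-length numeric vectors (>= 2 pairs).
#' @return a \code{mvpa_test}.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  s <- sd(d)
  if (s == 0) stop("zero variance of paired differences")
  t <- mean(d) / (s / sqrt(n))
  mvpa_test(t, n - 1, 2 * pt(abs(t), n - 1, lower.tail = FALSE), "two",
            "paired t")
}

#' Two-way repeated-measures ANOVA (hemisphere x region)
#'
#' Classical univariate within-subject decomposition for a complete
#' 2 (hemisphere) x 3 (region) design with subject as the random factor.
#' Each effect is tested against its own subject-interaction error term;
#' the hemisphere-by-region interaction has df (2, 2(n - 1)).  No
#' sphericity correction is applied by default (Greenhouse-Geisser is
#' available via \code{gg_correct}).
#'
#' @param table accuracy table: data frame with columns \code{subject},
#'   \code{region}, \code{hemisphere}, \code{accuracy}; one row per cell of
#'   the complete crossing.
#' @param gg_correct apply Greenhouse-Geisser correction to the df and p.
#' @return list of \code{mvpa_test} objects: \code{hemisphere},
#'   \code{region}, \code{interaction}; plus the full \code{ss} table.
#' @export
rm_anova_2x3 <- function(table, gg_correct = FALSE) {
  stopifnot(all(c("subject", "region", "hemisphere", "accuracy") %in%
                  names(table)))
  table$subject <- factor(table$subject)
  table$region <- factor(table$region)
  table$hemisphere <- factor(table$hemisphere)
  subs <- levels(table$subject)
  regs <- levels(table$region)
  hems <- levels(table$hemisphere)
  n <- length(subs); a <- length(hems); b <- length(regs)
  if (n < 2) stop("need at least 2 subjects")
  full <- expand.grid(subject = subs, hemisphere = hems, region = regs)
  key <- function(d) paste(d$subject, d$hemisphere, d$region)
  missing <- setdiff(key(full), key(table))
  if (length(missing))
    stop("incomplete design; missing cells: ", paste(missing, collapse = "; "))
  if (nrow(table) != nrow(full)) stop("duplicated cells in accuracy table")

  # cell means indexed [subject, hemisphere, region]
  Yv <- array(NA_real_, dim = c(n, a, b),
              dimnames = list(subs, hems, regs))
  for (i in seq_len(nrow(table)))
    Yv[as.character(table$subject[i]), as.character(table$hemisphere[i]),
       as.character(table$region[i])] <- table$accuracy[i]

  gm <- mean(Yv)
  m_s <- apply(Yv, 1, mean); m_a <- apply(Yv, 2, mean); m_b <- apply(Yv, 3, mean)
  m_sa <- apply(Yv, c(1, 2), mean); m_sb <- apply(Yv, c(1, 3), mean)
  m_ab <- apply(Yv, c(2, 3), mean)

  ss_s <- a * b * sum((m_s - gm)^2)
  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + gm)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + gm)^2)
  ss_tot <- sum((Yv - gm)^2)
  ss_sab <- ss_tot - ss_s - ss_a - ss_b - ss_sa - ss_sb - ss_ab

  df_a <- a - 1; df_b <- b - 1; df_ab <- df_a * df_b
  df_sa <- df_a * (n - 1); df_sb <- df_b * (n - 1); df_sab <- df_ab * (n - 1)

  eff <- function(ss_e, df_e, ss_err, df_err, label, contrasts = NULL) {
    # a null effect is F = 0 even when the error stratum is also empty
    f <- if (ss_e <= 1e-12 * max(ss_tot, .Machine$double.eps)) 0
         else (ss_e / df_e) / (ss_err / df_err)
    eps <- 1
    if (gg_correct && !is.null(contrasts)) eps <- gg_epsilon(contrasts)
    p <- pf(f, df_e * eps, df_err * eps, lower.tail = FALSE)
    out <- mvpa_test(f, c(df_e * eps, df_err * eps), p, "one", label)
    out$epsilon <- eps
    out
  }

  # per-subject contrast scores for Greenhouse-Geisser epsilon
  ctr_a <- m_sa %*% stats::contr.poly(a)                     # n x (a-1)
  ctr_b <- m_sb %*% stats::contr.poly(b)                     # n x (b-1)
  ctr_ab <- t(apply(Yv, 1, function(M)
    as.vector(t(stats::contr.poly(a)) %*% M %*% stats::contr.poly(b))))
  if (df_ab == 1) ctr_ab <- matrix(ctr_ab, ncol = 1)

  list(hemisphere = eff(ss_a, df_a, ss_sa, df_sa,
                        "RM-ANOVA main effect: hemisphere", ctr_a),
       region = eff(ss_b, df_b, ss_sb, df_sb,
                    "RM-ANOVA main effect: region", ctr_b),
       interaction = eff(ss_ab, df_ab, ss_sab, df_sab,
                         "RM-ANOVA interaction: hemisphere x region", ctr_ab),
       ss = data.frame(
         term = c("subject", "hemisphere", "region", "subj:hemi",
                  "subj:region", "hemi:region", "subj:hemi:region", "total"),
         ss = c(ss_s, ss_a, ss_b, ss_sa, ss_sb, ss_ab, ss_sab, ss_tot),
         df = c(n - 1, df_a, df_b, df_sa, df_sb, df_ab, df_sab, n * a * b - 1)))
}

# Greenhouse-Geisser epsilon from per-subject orthonormal contrast scores
gg_epsilon <- function(scores) {
  S <- stats::cov(scores)
  k <- ncol(S)
  sum(diag(S))^2 / (k * sum(S^2))
}

#' Pearson correlation with two-tailed t-based p-value
#'
#' Sample Pearson correlation; the p-value uses
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n - 2 df, two-tailed.
#'
#' @param x,y equal-length numeric vectors (>= 3), nonconstant.
#' @return list with \code{r}, \code{p}, \code{df}, \code{statistic}.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
    t <- Inf * sign(r)
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(t), n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, df = n - 2, statistic = t)
}

#' Dice overlap coefficient between two segmentations
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}.  Two empty masks are defined to overlap
#' perfectly (Dice 1) with a warning.
#'
#' @param a,b [roi_mask()] objects (or logical arrays) on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  ma <- if (inherits(a, "roi_mask")) a$mask else a
  mb <- if (inherits(b, "roi_mask")) b$mask else b
  if (!identical(dim(ma), dim(mb))) stop("masks are on different grids")
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) {
    warning("both masks are empty; Dice defined as 1")
    return(1)
  }
  2 * sum(ma & mb) / (na + nb)
}

#' One-way ANOVA comparing two independent groups
#'
#' Classical one-way ANOVA (default) or Welch's version, used for
#' patient-versus-control comparisons of per-subject accuracies.
#'
#' @param a,b numeric vectors for the two groups.
#' @param welch use Welch's correction for unequal variances.
#' @return a \code{mvpa_test}.
#' @export
group_anova <- function(a, b, welch = FALSE) {
  dat <- data.frame(y = c(a, b),
                    g = factor(rep(c("a", "b"), c(length(a), length(b)))))
  fit <- stats::oneway.test(y ~ g, data = dat, var.equal = !welch)
  mvpa_test(unname(fit$statistic), unname(unlist(fit$parameter)),
            fit$p.value, "one", "one-way ANOVA (two groups)")
}

mvpa_test <- function(statistic, df, p, tail, method) {
  structure(list(statistic = statistic, df = df, p = p, tail = tail,
                 method = method), class = "mvpa_test")
}

#' @export
print.mvpa_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g (%s-tailed)\n",
              x$method, x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p, x$tail))
  invisible(x)
}
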