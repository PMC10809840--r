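#' Box-Cox transform with maximum-likelihood lambda
#'
#' Transforms a positive sample toward normality. When values are not
#' strictly positive they are first shifted by `-min(x) + eps` (the shift
#' is returned). Lambda is chosen by profile maximum likelihood on a grid;
#' `lambda = 0` uses the log branch.
#'
#' @param x numeric values.
#' @param eps shift margin used when values are not strictly positive.
#' @param grid lambda search grid.
#' @return List with `values` (transformed), `lambda`, `shift`.
#' @export
boxcox_transform <- function(x, eps = 1e-6,
                             grid = seq(-2, 2, by = 0.01)) {
  if (length(unique(x)) < 2) stop("constant input cannot be transformed")
  shift <- 0
  if (min(x) <= 0) shift <- -min(x) + eps + diff(range(x)) * 1e-3
  y <- x + shift
  bc <- MASS::boxcox(y ~ 1, lambda = grid, plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  out <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  list(values = out, lambda = lambda, shift = shift)
}

#' Repeated-measures ANOVA with subject as a random factor
#'
#' Aggregates the epoch-level feature table to one observation per subject
#' and factor cell (mean of epoch values), Box-Cox transforms the
#' aggregated response, and runs a classical repeated-measures ANOVA:
#' every within-subject effect is tested against its own
#' subject-by-effect error stratum (`aov` with an `Error(subject/...)`
#' design). For a two-level factor this is exactly the paired t test, and
#' it remains calibrated when within-subject correlation is negative --
#' which per-recording z-scoring induces between period means -- where a
#' non-negative random-intercept model would be anticonservative. When
#' the aggregated table is unbalanced (missing cells), the function falls
#' back to a subject-random-intercept mixed model (Satterthwaite F) and
#' flags the result. Main effects and all two-way interactions of the
#' requested factors are tested; Tukey-adjusted pairwise comparisons of
#' means are computed per main factor.
#'
#' @param table feature table from [feature_table()] (rows for several
#'   subjects combined).
#' @param feature feature name to analyse.
#' @param factors any of `"period"`, `"label"` (stage), `"contact"`
#'   (channel), `"fusion"`.
#' @param fusion restrict to one agreement level (`NA` keeps all; required
#'   unless `"fusion"` is a factor).
#' @param stages_only drop nonseizure epochs first (for stage analyses).
#' @param boxcox transform the response before fitting.
#' @return `nw_anova`: list with `anova` (factor, F, df, P), `posthoc`
#'   (Tukey pairwise tables per factor), `lambda`, `flags`, and `model`.
#' @export
repeated_anova <- function(table, feature = "envelope",
                           factors = c("period", "contact"),
                           fusion = if ("fusion" %in% factors) NA else 3,
                           stages_only = FALSE, boxcox = TRUE) {
  factors <- match.arg(factors, c("period", "label", "contact", "fusion"),
                       several.ok = TRUE)
  df <- table[table$feature == feature & is.finite(table$value), ]
  if (!is.na(fusion) && !"fusion" %in% factors) df <- df[df$fusion == fusion, ]
  if (stages_only || "label" %in% factors)
    df <- df[df$label != "nonseizure", ]
  names(df)[names(df) == "channel"] <- "contact"
  agg <- stats::aggregate(value ~ ., data =
    df[, c("subject", factors, "value")], FUN = mean)
  if (length(unique(agg$subject)) < 2)
    stop("repeated ANOVA needs at least 2 subjects (random-factor levels)")
  for (f in factors) {
    agg[[f]] <- factor(agg[[f]])
    if (nlevels(agg[[f]]) < 2)
      stop("factor `", f, "` has fewer than 2 levels")
  }
  agg$subject <- factor(agg$subject)
  flags <- character()
  cells <- base::table(agg[c("subject", factors)])
  balanced <- all(cells == 1)
  if (!balanced)
    flags <- c(flags,
               "empty_cells: unbalanced design, mixed-model fallback used")
  lambda <- NA_real_
  if (boxcox) {
    bc <- boxcox_transform(agg$value)
    agg$value <- bc$values
    lambda <- bc$lambda
  }
  rhs <- if (length(factors) > 1)
    paste0("(", paste(factors, collapse = " + "), ")^2") else factors
  if (balanced) {
    estrata <- paste0("Error(subject/(",
                      paste(factors, collapse = " * "), "))")
    form <- stats::as.formula(paste("value ~", rhs, "+", estrata))
    # embed the formula value in the call so emmeans can recover it
    fit <- do.call(stats::aov, list(formula = form, data = agg))
    res <- do.call(rbind, lapply(summary(fit), function(st) {
      tb <- st[[1]]
      term <- trimws(rownames(tb))
      keep <- term != "Residuals" & !is.na(tb$`F value`)
      if (!any(keep)) return(NULL)
      data.frame(factor = term[keep], F = tb$`F value`[keep],
                 df1 = tb$Df[keep],
                 df2 = tb$Df[term == "Residuals"],
                 P = tb$`Pr(>F)`[keep], row.names = NULL)
    }))
  } else {
    form <- stats::as.formula(paste("value ~", rhs, "+ (1 | subject)"))
    fit <- lmerTest::lmer(form, data = agg)
    an <- stats::anova(fit)
    res <- data.frame(factor = rownames(an), F = an$`F value`,
                      df1 = an$NumDF, df2 = an$DenDF,
                      P = an$`Pr(>F)`, row.names = NULL)
  }
  posthoc <- lapply(stats::setNames(factors, factors), function(f) {
    em <- suppressMessages(
      emmeans::emmeans(fit, stats::as.formula(paste("~", f))))
    as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  })
  structure(list(anova = res, posthoc = posthoc, lambda = lambda,
                 flags = flags, model = fit),
            class = "nw_anova")
}

#' @export
print.nw_anova <- function(x, ...) {
  cat("<nw_anova> mixed-model repeated ANOVA (subject random intercept)\n")
  tab <- x$anova
  tab$F <- signif(tab$F, 4); tab$df2 <- round(tab$df2, 1)
  tab$P <- format.pval(tab$P, digits = 3)
  print(tab, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Relative topography of a feature
#'
#' Per-contact relative change of a feature during seizure (or one stage)
#' versus the nonseizure baseline:
#' `100 * (F_seizure - F_nonseizure) / F_nonseizure` (percent). Group
#' means are taken over per-subject means. Contacts with a zero baseline
#' are flagged `NA`.
#'
#' @param table feature table (several subjects).
#' @param feature feature name.
#' @param fusion agreement level (default 3 = consensus of all raters).
#' @param stage `NULL` for the whole seizure period, or `"S1"`, `"S2"`,
#'   `"S3"`.
#' @return Data frame `contact`, `percent` (one row per contact).
#' @export
topography <- function(table, feature = "envelope", fusion = 3,
                       stage = NULL) {
  df <- table[table$feature == feature & table$fusion == fusion &
                is.finite(table$value), ]
  sel <- if (is.null(stage)) df$period == "seizure" else df$label == stage
  per_subj <- function(sub) {
    stats::aggregate(value ~ channel + subject, data = sub, FUN = mean)
  }
  seiz <- per_subj(df[sel, ])
  base <- per_subj(df[df$period == "nonseizure", ])
  ms <- stats::aggregate(value ~ channel, data = seiz, FUN = mean)
  mb <- stats::aggregate(value ~ channel, data = base, FUN = mean)
  m <- merge(ms, mb, by = "channel", suffixes = c("_seiz", "_base"))
  pct <- ifelse(m$value_base != 0,
                100 * (m$value_seiz - m$value_base) / m$value_base, NA_real_)
  data.frame(contact = m$channel, percent = pct)
}
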