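# Per-clone allelic ratio and the between-genotype comparison.
#
# Within a heterozygous clone the edited allele is distinguishable from
# the wild-type allele, so the fraction of informative reads carrying the
# edit measures that allele's relative chromatin accessibility; a
# het-control clone should sit near 0.5, and a het-variant clone below its
# het-control counterpart if the variant reduces accessibility. Clones,
# not reads, are the unit of replication for the group test.

#' Per-clone allelic ratio with exact binomial interval
#'
#' The mutant category is implied by the clone group: for a
#' \code{het_control} clone the mutant (edited) reads are the
#' control-edited reads, for a \code{het_variant} clone the variant reads.
#' Total reads are the sum of wild-type and edited-allele reads, and the
#' ratio is mutant/total with a Clopper-Pearson 95\% interval (exact
#' coverage even at ratios near 0 or 1). The count in the other edited
#' category - which should be ~0 for a het clone - is reported as a
#' contamination diagnostic. Homozygous clones have no informative
#' within-clone ratio and require an explicit \code{mutant_category}.
#'
#' @param counts An \code{\link{count_alleles}} result.
#' @param group Clone genotype group.
#' @param mutant_category Override of the mutant category
#'   (\code{"CONTROL_EDITED"} or \code{"VARIANT"}); required for hom
#'   groups.
#' @param conf_level Interval coverage (default 0.95).
#' @return Object of class \code{allelic_ratio}.
#' @export
allelic_ratio <- function(counts, group = c("het_control", "het_variant",
                                            "hom_control", "hom_variant"),
                          mutant_category = NULL, conf_level = 0.95) {
  group <- match.arg(group)
  if (is.null(mutant_category)) {
    mutant_category <- switch(group,
      het_control = "CONTROL_EDITED",
      het_variant = "VARIANT",
      stop("mutant category is ambiguous for a '", group,
           "' clone; pass mutant_category explicitly", call. = FALSE))
  }
  n_mutant <- switch(mutant_category,
                     CONTROL_EDITED = counts$n_control_edited,
                     VARIANT = counts$n_variant,
                     stop("unknown mutant_category", call. = FALSE))
  contamination <- switch(mutant_category,
                          CONTROL_EDITED = counts$n_variant,
                          VARIANT = counts$n_control_edited)
  n_total <- counts$n_wt + n_mutant
  if (n_total == 0L)
    stop("undefined ratio: no wild-type or mutant reads for clone '",
         counts$clone_id, "'", call. = FALSE)
  bt <- stats::binom.test(n_mutant, n_total, conf.level = conf_level)
  structure(list(clone_id = counts$clone_id, group = group,
                 mutant_category = mutant_category,
                 n_mutant = n_mutant, n_wt = counts$n_wt,
                 n_total = n_total,
                 ratio = n_mutant / n_total,
                 ci_low = bt$conf.int[1L], ci_high = bt$conf.int[2L],
                 conf_level = conf_level,
                 n_contamination = contamination),
            class = "allelic_ratio")
}

#' @export
print.allelic_ratio <- function(x, ...) {
  cat(sprintf(
    "Clone '%s' (%s): %d/%d mutant reads, ratio %.4f [%.4f, %.4f]\n",
    x$clone_id, x$group, x$n_mutant, x$n_total, x$ratio, x$ci_low,
    x$ci_high))
  if (x$n_contamination > 0)
    cat(sprintf("  contamination: %d reads in the other edited category\n",
                x$n_contamination))
  invisible(x)
}

#' @export
as.data.frame.allelic_ratio <- function(x, ...) {
  data.frame(clone_id = x$clone_id, group = x$group,
             n_mutant = x$n_mutant, n_wt = x$n_wt, n_total = x$n_total,
             ratio = x$ratio, ci_low = x$ci_low, ci_high = x$ci_high,
             n_contamination = x$n_contamination, stringsAsFactors = FALSE)
}

ratio_values <- function(x) {
  if (inherits(x, "allelic_ratio")) x <- list(x)
  vapply(x, function(r) {
    if (!inherits(r, "allelic_ratio"))
      stop("expected allelic_ratio objects", call. = FALSE)
    r$ratio
  }, numeric(1))
}

#' Compare allelic ratios between genotype groups
#'
#' Two-sided Student's t test on the per-clone ratios of two groups
#' (typically het-control vs het-variant clones, at least two clones per
#' group). With \code{use_stats_policy = TRUE} the full decision engine
#' (normality/variance gates, transform fallback, test selection) is run
#' instead of an unconditional Student's t test.
#'
#' @param control_clones,variant_clones Lists of
#'   \code{\link{allelic_ratio}} objects (or numeric ratio vectors).
#' @param use_stats_policy Delegate test choice to
#'   \code{\link{select_and_run}}.
#' @param labels Group labels for reporting.
#' @return Object of class \code{allelic_comparison}: test name, statistic,
#'   df, p-value, group means and direction of effect.
#' @export
compare_allelic_ratios <- function(control_clones, variant_clones,
                                   use_stats_policy = FALSE,
                                   labels = c("het_control", "het_variant")) {
  a <- if (is.numeric(control_clones)) control_clones
       else ratio_values(control_clones)
  b <- if (is.numeric(variant_clones)) variant_clones
       else ratio_values(variant_clones)
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 clones per group", call. = FALSE)

  if (use_stats_policy) {
    dat <- data.frame(group = rep(labels, c(length(a), length(b))),
                      value = c(a, b), stringsAsFactors = FALSE)
    trace <- select_and_run(dat, design = "two_group")
    test_name <- trace$test_name
    statistic <- trace$statistic
    df <- trace$df
    p <- trace$raw_p
  } else {
    trace <- NULL
    test_name <- "Student's t"
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate zero-variance groups: t.test cannot run
      df <- length(c(a, b)) - 2L
      if (mean(a) == mean(b)) { statistic <- 0; p <- 1 }
      else { statistic <- sign(mean(a) - mean(b)) * Inf; p <- 0 }
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      statistic <- unname(tt$statistic)
      df <- unname(tt$parameter)
      p <- tt$p.value
    }
  }
  direction <- if (mean(b) < mean(a)) sprintf("%s < %s", labels[2L],
                                              labels[1L])
               else if (mean(b) > mean(a)) sprintf("%s > %s", labels[2L],
                                                   labels[1L])
               else "no difference"
  structure(list(group_a = labels[1L], group_b = labels[2L],
                 ratios_a = a, ratios_b = b,
                 mean_a = mean(a), mean_b = mean(b),
                 test_name = test_name, statistic = statistic, df = df,
                 p_value = p, direction = direction, trace = trace),
            class = "allelic_comparison")
}

#' @export
print.allelic_comparison <- function(x, ...) {
  cat(sprintf("Allelic-ratio comparison: %s (n=%d, mean %.4f) vs %s (n=%d, mean %.4f)\n",
              x$group_a, length(x$ratios_a), x$mean_a,
              x$group_b, length(x$ratios_b), x$mean_b))
  cat(sprintf("  %s: t = %.4f, df = %.4g, p = %.4g (%s)\n", x$test_name,
              x$statistic, x$df, x$p_value, x$direction))
  invisible(x)
}
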