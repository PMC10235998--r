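# Dual-locus allele classification of ATAC reads.
#
# Only a read spanning BOTH tagged sites is informative: with reference
# bases at both (C at the PAM site, G at the variant site) it is a
# wild-type-allele read; with the PAM edit alone (G, G) a control-edited
# read; with both edits (G, A) a variant-allele read. The (C, A)
# combination - the variant without the PAM edit - cannot arise from either
# donor template, so it is excluded from all three counted categories and
# tracked separately.

ALLELE_CATEGORIES <- c("WT", "CONTROL_EDITED", "VARIANT", "UNINFORMATIVE")
UNINFORMATIVE_REASONS <- c("not_spanning", "low_mapq", "low_base_quality",
                           "unexpected_base", "deletion_at_site",
                           "variant_without_pam")

#' Classify one read at the two edited loci
#'
#' Resolves the base aligned to the PAM and the variant position (via the
#' CIGAR walk) and assigns the read to WT, CONTROL_EDITED, VARIANT, or
#' UNINFORMATIVE with a reason: \code{not_spanning} when either site lies
#' outside the aligned span, \code{deletion_at_site} when a deletion
#' overlaps a site, \code{low_base_quality} when either interrogated base
#' is below \code{min_base_quality}, \code{variant_without_pam} for the
#' (ref, alt) combination, and \code{unexpected_base} for any base outside
#' the defined ref/alt pair. Every input maps to a call; the function never
#' errors on read content.
#'
#' @param read One alignment record (single-row data.frame or list).
#' @param scheme An \code{\link{edit_scheme}}.
#' @param min_base_quality Minimum Phred base quality at the two sites
#'   (default 20; set 0 to disable).
#' @return List with \code{category} and \code{reason} (\code{NA} unless
#'   UNINFORMATIVE).
#' @export
classify_read <- function(read, scheme, min_base_quality = 20) {
  pam <- bases_at(read$pos, read$cigar, read$seq, read$qual, scheme$pam_pos)
  var <- bases_at(read$pos, read$cigar, read$seq, read$qual, scheme$var_pos)
  r <- classify_calls(pam$base, pam$qual, var$base, var$qual, scheme,
                      min_base_quality)
  list(category = r$category[1L], reason = r$reason[1L])
}

# Vectorised classification from resolved per-site bases/qualities.
# Precedence: spanning, then deletion, then base quality, then genotype.
classify_calls <- function(pam_base, pam_qual, var_base, var_qual, scheme,
                           min_base_quality) {
  n <- length(pam_base)
  category <- rep("UNINFORMATIVE", n)
  reason <- rep(NA_character_, n)

  not_span <- pam_base == "NOT_COVERED" | var_base == "NOT_COVERED"
  deleted <- !not_span & (pam_base == "DELETED" | var_base == "DELETED")
  low_bq <- !not_span & !deleted &
    (pam_qual < min_base_quality | var_qual < min_base_quality)
  resolved <- !(not_span | deleted | low_bq)

  reason[not_span] <- "not_spanning"
  reason[deleted] <- "deletion_at_site"
  reason[low_bq] <- "low_base_quality"

  p_ref <- pam_base == scheme$pam_ref
  p_alt <- pam_base == scheme$pam_alt
  v_ref <- var_base == scheme$var_ref
  v_alt <- var_base == scheme$var_alt

  category[resolved & p_ref & v_ref] <- "WT"
  category[resolved & p_alt & v_ref] <- "CONTROL_EDITED"
  category[resolved & p_alt & v_alt] <- "VARIANT"
  vwp <- resolved & p_ref & v_alt
  reason[vwp] <- "variant_without_pam"
  unexpected <- resolved & !(p_ref | p_alt) | resolved & !(v_ref | v_alt)
  category[unexpected] <- "UNINFORMATIVE"
  reason[unexpected] <- "unexpected_base"
  list(category = category, reason = reason)
}

#' Tally allele classes over a clone's reads
#'
#' Applies \code{\link{classify_read}} to every record of one clone after
#' excluding secondary/supplementary and unmapped records, tagging reads at
#' or below \code{min_mapq} as UNINFORMATIVE/low_mapq. In \code{fragment}
#' mode, mates sharing a query name are merged: concordant informative
#' calls count once, discordant informative calls become
#' UNINFORMATIVE/unexpected_base, and a fragment with a single informative
#' mate takes that mate's call.
#'
#' The total informative count is the sum of wild-type and edited-allele
#' reads, the denominator of the published allelic ratio.
#'
#' @param reads Record data.frame (one clone).
#' @param scheme An \code{\link{edit_scheme}}.
#' @param min_base_quality Phred threshold at the two sites.
#' @param min_mapq MAPQ threshold, strict (records with \code{mapq <=
#'   min_mapq} are uninformative); set below 0 to disable when the input
#'   was already filtered.
#' @param unit \code{"read"} (each mate counted independently; default, the
#'   published rule counts "reads") or \code{"fragment"}.
#' @param dedup Drop duplicate-flagged (0x400) records first.
#' @param clone_id Identifier stored in the result.
#' @return Object of class \code{allele_counts}: counts per category,
#'   per-reason uninformative histogram, and bookkeeping totals.
#' @export
count_alleles <- function(reads, scheme, min_base_quality = 20,
                          min_mapq = 10L, unit = c("read", "fragment"),
                          dedup = FALSE, clone_id = "clone") {
  unit <- match.arg(unit)
  if (nrow(reads) == 0L) {
    warning("no input reads; returning zero counts")
    return(new_allele_counts(clone_id, 0L, 0L, 0L,
                             setNames(integer(length(UNINFORMATIVE_REASONS)),
                                      UNINFORMATIVE_REASONS),
                             n_excluded = 0L, unit = unit))
  }
  drop <- is_secondary_or_supplementary(reads) | is_unmapped(reads)
  if (dedup) drop <- drop | is_duplicate(reads)
  n_excluded <- sum(drop)
  reads <- reads[!drop, , drop = FALSE]

  pam <- bases_at(reads$pos, reads$cigar, reads$seq, reads$qual,
                  scheme$pam_pos)
  var <- bases_at(reads$pos, reads$cigar, reads$seq, reads$qual,
                  scheme$var_pos)
  calls <- classify_calls(pam$base, pam$qual, var$base, var$qual, scheme,
                          min_base_quality)
  low <- reads$mapq <= min_mapq
  calls$category[low] <- "UNINFORMATIVE"
  calls$reason[low] <- "low_mapq"

  if (unit == "fragment") {
    merged <- merge_mate_calls(reads$qname, calls)
    calls <- merged
  }

  reasons <- setNames(integer(length(UNINFORMATIVE_REASONS)),
                      UNINFORMATIVE_REASONS)
  tab <- table(factor(calls$reason[calls$category == "UNINFORMATIVE"],
                      levels = UNINFORMATIVE_REASONS))
  reasons[names(tab)] <- as.integer(tab)

  new_allele_counts(
    clone_id,
    n_wt = sum(calls$category == "WT"),
    n_control_edited = sum(calls$category == "CONTROL_EDITED"),
    n_variant = sum(calls$category == "VARIANT"),
    reasons = reasons, n_excluded = n_excluded, unit = unit)
}

merge_mate_calls <- function(qname, calls) {
  category <- character(0); reason <- character(0)
  for (idx in split(seq_along(qname), qname)) {
    cat_i <- calls$category[idx]; rea_i <- calls$reason[idx]
    inf <- cat_i != "UNINFORMATIVE"
    if (any(inf)) {
      u <- unique(cat_i[inf])
      if (length(u) == 1L) {
        category <- c(category, u); reason <- c(reason, NA_character_)
      } else {
        category <- c(category, "UNINFORMATIVE")
        reason <- c(reason, "unexpected_base")
      }
    } else {
      category <- c(category, "UNINFORMATIVE")
      reason <- c(reason, rea_i[1L])
    }
  }
  list(category = category, reason = reason)
}

new_allele_counts <- function(clone_id, n_wt, n_control_edited, n_variant,
                              reasons, n_excluded, unit) {
  structure(list(clone_id = clone_id,
                 n_wt = as.integer(n_wt),
                 n_control_edited = as.integer(n_control_edited),
                 n_variant = as.integer(n_variant),
                 n_total_informative = as.integer(n_wt + n_control_edited +
                                                    n_variant),
                 n_uninformative_by_reason = reasons,
                 n_uninformative = as.integer(sum(reasons)),
                 n_excluded = as.integer(n_excluded),
                 unit = unit),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("Allele counts for clone '%s' (unit: %s)\n", x$clone_id,
              x$unit))
  cat(sprintf("  WT %d | control-edited %d | variant %d  (informative %d)\n",
              x$n_wt, x$n_control_edited, x$n_variant,
              x$n_total_informative))
  nz <- x$n_uninformative_by_reason[x$n_uninformative_by_reason > 0]
  if (length(nz))
    cat("  uninformative:",
        paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Convert allele counts to a one-row table
#' @param x An \code{allele_counts} object.
#' @param ... Unused.
#' @return One-row data.frame matching the counts TSV layout.
#' @export
as.data.frame.allele_counts <- function(x, ...) {
  r <- x$n_uninformative_by_reason
  data.frame(clone_id = x$clone_id, n_wt = x$n_wt,
             n_control_edited = x$n_control_edited,
             n_variant = x$n_variant,
             n_total_informative = x$n_total_informative,
             n_not_spanning = r[["not_spanning"]],
             n_low_mapq = r[["low_mapq"]],
             n_low_bq = r[["low_base_quality"]],
             n_unexpected = r[["unexpected_base"]],
             n_deletion = r[["deletion_at_site"]],
             n_variant_without_pam = r[["variant_without_pam"]],
             stringsAsFactors = FALSE)
}

#' Genotype a Sanger-style amplicon sequence at the two edited loci
#'
#' Classifies a consensus amplicon sequence into the engineered clone
#' categories. Homozygous calls come from unambiguous single bases;
#' heterozygous calls use IUPAC ambiguity codes as a proxy for double
#' chromatogram peaks: S (C/G) at the PAM position and R (G/A) at the
#' variant position.
#'
#' @param seq Nucleotide string covering both edit positions.
#' @param scheme An \code{\link{edit_scheme}}.
#' @param anchor_start Genomic coordinate of the first base of \code{seq}.
#' @return One of \code{hom_control}, \code{het_control},
#'   \code{hom_variant}, \code{het_variant}, \code{wild_type},
#'   \code{ambiguous}.
#' @export
genotype_amplicon <- function(seq, scheme, anchor_start) {
  i_pam <- scheme$pam_pos - anchor_start + 1L
  i_var <- scheme$var_pos - anchor_start + 1L
  if (i_pam < 1L || i_var < 1L || i_pam > nchar(seq) || i_var > nchar(seq))
    stop("amplicon does not cover both edit positions", call. = FALSE)
  b_pam <- substr(seq, i_pam, i_pam)
  b_var <- substr(seq, i_var, i_var)
  pam_state <- site_state(b_pam, scheme$pam_ref, scheme$pam_alt)
  var_state <- site_state(b_var, scheme$var_ref, scheme$var_alt)
  if (pam_state == "ref" && var_state == "ref") return("wild_type")
  if (pam_state == "alt" && var_state == "ref") return("hom_control")
  if (pam_state == "alt" && var_state == "alt") return("hom_variant")
  if (pam_state == "het" && var_state == "ref") return("het_control")
  if (pam_state == "het" && var_state == "het") return("het_variant")
  "ambiguous"
}

IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

site_state <- function(base, ref, alt) {
  if (base == ref) return("ref")
  if (base == alt) return("alt")
  pair <- paste(sort(c(ref, alt)), collapse = "")
  if (base == IUPAC2[[pair]]) return("het")
  "other"
}
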