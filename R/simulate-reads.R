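#' Build a synthetic reference window around the edited locus
#'
#' Embeds the pre-edit genomic context (by default the printed control
#' donor oligo with its PAM base reverted to the reference C) between
#' seeded-random flanking sequence, and anchors the result so that the PAM
#' base falls at its genomic coordinate. With the defaults the window
#' places C at chr19:50739290 and G at chr19:50739310, the pre-edit state
#' of the two tagged sites.
#'
#' @param ssodn_context Nucleotide string giving the local genomic context;
#'   must carry the reference base at both anchor positions.
#' @param flank_length Number of random bases added on each side; must be at
#'   least one read length so simulated fragments can fit.
#' @param seed Integer seed for the random flanks.
#' @param scheme An \code{\link{edit_scheme}}.
#' @param pam_offset 1-based offset of the PAM base within
#'   \code{ssodn_context}.
#' @param min_flank Minimum admissible \code{flank_length}, normally the
#'   simulated read length.
#' @return An object of class \code{reference_window} with fields
#'   \code{contig}, \code{start} (genomic coordinate of the first base) and
#'   \code{seq}.
#' @export
build_reference_window <- function(ssodn_context = ssodn_reference(),
                                   flank_length = 200L,
                                   seed = 1L,
                                   scheme = edit_scheme(),
                                   pam_offset = SSODN_PAM_OFFSET,
                                   min_flank = 75L) {
  if (!is_single_string(ssodn_context))
    stop("'ssodn_context' must be a single nucleotide string", call. = FALSE)
  flank_length <- as.integer(flank_length)
  if (flank_length < min_flank)
    stop(sprintf("insufficient flank: flank_length must be >= %d", min_flank),
         call. = FALSE)
  site_gap <- scheme$var_pos - scheme$pam_pos
  var_offset <- pam_offset + site_gap
  n <- nchar(ssodn_context)
  if (pam_offset < 1L || var_offset < 1L || pam_offset > n || var_offset > n)
    stop("context does not cover both edit positions", call. = FALSE)
  if (substr(ssodn_context, pam_offset, pam_offset) != scheme$pam_ref ||
      substr(ssodn_context, var_offset, var_offset) != scheme$var_ref)
    stop(sprintf(
      "context lacks the expected reference bases (%s at PAM offset %d, %s at variant offset %d)",
      scheme$pam_ref, pam_offset, scheme$var_ref, var_offset), call. = FALSE)

  flanks <- with_seed(seed, {
    list(left  = paste(sample(c("A", "C", "G", "T"), flank_length, TRUE),
                       collapse = ""),
         right = paste(sample(c("A", "C", "G", "T"), flank_length, TRUE),
                       collapse = ""))
  })
  seq <- paste0(flanks$left, ssodn_context, flanks$right)
  start <- scheme$pam_pos - (flank_length + pam_offset) + 1L
  w <- structure(list(contig = scheme$contig, start = as.integer(start),
                      seq = seq),
                 class = "reference_window")
  w
}

#' @export
print.reference_window <- function(x, ...) {
  cat(sprintf("Reference window %s:%d-%d (%d bp)\n", x$contig, x$start,
              window_end(x), nchar(x$seq)))
  invisible(x)
}

#' @rdname window_base
#' @export
window_end <- function(window) window$start + nchar(window$seq) - 1L

#' Look up a window base at a genomic coordinate
#' @param window A \code{reference_window}.
#' @param position 1-based genomic coordinate.
#' @return Single base, or \code{NA} when the position lies outside the
#'   window.
#' @export
window_base <- function(window, position) {
  i <- position - window$start + 1L
  ifelse(i >= 1L & i <= nchar(window$seq),
         substring(window$seq, i, i), NA_character_)
}

#' Haplotype and clone genotype specifications
#'
#' A haplotype is WT (no edits), PAM_ONLY (the PAM-blocking edit alone) or
#' PAM_PLUS_VARIANT (PAM edit plus the variant substitution); each carries a
#' nonnegative accessibility weight, its relative fragment-sampling rate in
#' the simulator. A clone genotype pairs two haplotypes according to the
#' four engineered categories: \code{hom_control} = (PAM_ONLY, PAM_ONLY),
#' \code{het_control} = (WT, PAM_ONLY), \code{hom_variant} =
#' (PAM_PLUS_VARIANT, PAM_PLUS_VARIANT) and \code{het_variant} =
#' (WT, PAM_PLUS_VARIANT).
#'
#' @param label Haplotype label.
#' @param scheme An \code{\link{edit_scheme}}.
#' @param accessibility_weight Nonnegative relative sampling weight.
#' @return \code{haplotype_spec}: list with \code{label}, \code{edits}
#'   (data.frame of position/alt_base) and \code{accessibility_weight}.
#' @export
haplotype_spec <- function(label = c("WT", "PAM_ONLY", "PAM_PLUS_VARIANT"),
                           scheme = edit_scheme(),
                           accessibility_weight = 1) {
  label <- match.arg(label)
  stopifnot_scalar_number(accessibility_weight, "accessibility_weight",
                          lower = 0)
  edits <- switch(label,
    WT = data.frame(position = integer(), alt_base = character()),
    PAM_ONLY = data.frame(position = scheme$pam_pos,
                          alt_base = scheme$pam_alt),
    PAM_PLUS_VARIANT = data.frame(
      position = c(scheme$pam_pos, scheme$var_pos),
      alt_base = c(scheme$pam_alt, scheme$var_alt)))
  structure(list(label = label, edits = edits,
                 accessibility_weight = accessibility_weight),
            class = "haplotype_spec")
}

#' @rdname haplotype_spec
#' @param clone_id Clone identifier.
#' @param group One of the four engineered genotype groups.
#' @param weights Length-2 accessibility weights for the two haplotypes of
#'   the pair, in the order given above (for het clones: WT first, edited
#'   second).
#' @return \code{clone_genotype}: list with \code{clone_id}, \code{group}
#'   and \code{haplotype_pair}.
#' @export
clone_genotype <- function(clone_id,
                           group = c("hom_control", "het_control",
                                     "hom_variant", "het_variant"),
                           scheme = edit_scheme(),
                           weights = c(1, 1)) {
  group <- match.arg(group)
  if (length(weights) != 2L || any(weights < 0) || sum(weights) <= 0)
    stop("'weights' must be two nonnegative values with positive sum",
         call. = FALSE)
  labels <- switch(group,
    hom_control = c("PAM_ONLY", "PAM_ONLY"),
    het_control = c("WT", "PAM_ONLY"),
    hom_variant = c("PAM_PLUS_VARIANT", "PAM_PLUS_VARIANT"),
    het_variant = c("WT", "PAM_PLUS_VARIANT"))
  pair <- list(haplotype_spec(labels[1L], scheme, weights[1L]),
               haplotype_spec(labels[2L], scheme, weights[2L]))
  structure(list(clone_id = as.character(clone_id), group = group,
                 haplotype_pair = pair),
            class = "clone_genotype")
}

#' ATAC read-simulation configuration
#'
#' Parameters of the synthetic paired-end ATAC-seq read generator. Fragment
#' midpoints follow a Gaussian centred on the accessible-chromatin peak
#' (default centre 50739348, the midpoint of the chr19:50739241-50739456
#' candidate cis-regulatory element), or a uniform model. Sequencing errors
#' are i.i.d. per-base substitutions; reads carry constant base quality
#' (Phred 37) except at injected errors (Phred 11), so base-quality
#' filtering can be exercised.
#'
#' @param reference_window A \code{\link{build_reference_window}} result.
#' @param n_fragments Number of fragments (each yields two mate reads).
#' @param read_length Read length in bases (75 for the emulated libraries).
#' @param fragment_length_mean,fragment_length_sd Fragment length
#'   distribution (bp).
#' @param peak_center,peak_sd Fragment-midpoint model (1-based coordinate,
#'   bp dispersion).
#' @param error_rate Per-base substitution probability, in [0, 0.25].
#' @param mapq_value MAPQ assigned to reads (0-60).
#' @param frac_low_mapq Fraction of reads assigned \code{low_mapq_value}.
#' @param low_mapq_value MAPQ for the low-quality subset; must be <= 10 so
#'   the filter removes it.
#' @param position_model \code{"gaussian"} (default) or \code{"uniform"}.
#' @param seed Integer seed.
#' @return An object of class \code{atac_sim_config}.
#' @export
atac_sim_config <- function(reference_window,
                            n_fragments,
                            read_length = 75L,
                            fragment_length_mean = 180,
                            fragment_length_sd = 35,
                            peak_center = 50739348L,
                            peak_sd = 60,
                            error_rate = 0,
                            mapq_value = 42L,
                            frac_low_mapq = 0,
                            low_mapq_value = 5L,
                            position_model = c("gaussian", "uniform"),
                            seed = 1L) {
  position_model <- match.arg(position_model)
  stopifnot_scalar_number(n_fragments, "n_fragments", lower = 1)
  stopifnot_scalar_number(read_length, "read_length", lower = 1)
  stopifnot_scalar_number(fragment_length_mean, "fragment_length_mean",
                          lower = 1)
  stopifnot_scalar_number(fragment_length_sd, "fragment_length_sd", lower = 0)
  stopifnot_scalar_number(error_rate, "error_rate", lower = 0, upper = 0.25)
  stopifnot_scalar_number(mapq_value, "mapq_value", lower = 0, upper = 60)
  stopifnot_scalar_number(frac_low_mapq, "frac_low_mapq", lower = 0,
                          upper = 1)
  stopifnot_scalar_number(low_mapq_value, "low_mapq_value", lower = 0,
                          upper = 10)
  cfg <- structure(list(reference_window = reference_window,
                        n_fragments = as.integer(n_fragments),
                        read_length = as.integer(read_length),
                        fragment_length_mean = fragment_length_mean,
                        fragment_length_sd = fragment_length_sd,
                        peak_center = as.integer(peak_center),
                        peak_sd = peak_sd,
                        error_rate = error_rate,
                        mapq_value = as.integer(mapq_value),
                        frac_low_mapq = frac_low_mapq,
                        low_mapq_value = as.integer(low_mapq_value),
                        position_model = position_model,
                        seed = as.integer(seed)),
                   class = "atac_sim_config")
  validate_sim_window(cfg)
  cfg
}

# The window must be able to hold a fragment; edit positions are checked
# against the window at simulation time once the haplotypes are known.
validate_sim_window <- function(cfg) {
  w <- cfg$reference_window
  if (w$start + cfg$read_length > window_end(w) - cfg$read_length)
    stop("reference window shorter than twice the read length", call. = FALSE)
  invisible(cfg)
}

# Apply a haplotype's edits to the window sequence (window-local string).
haplotype_sequence <- function(window, hap) {
  seq <- window$seq
  if (nrow(hap$edits)) {
    idx <- hap$edits$position - window$start + 1L
    if (any(idx < 1L | idx > nchar(seq)))
      stop("edit position outside reference window", call. = FALSE)
    for (k in seq_along(idx))
      substr(seq, idx[k], idx[k]) <- hap$edits$alt_base[k]
  }
  seq
}

PHRED_HIGH <- "F"  # Phred 37
PHRED_ERR  <- ","  # Phred 11

#' Simulate aligned paired-end ATAC reads from a diploid clone
#'
#' Draws fragments from the clone's two haplotypes in proportion to their
#' accessibility weights, places fragment midpoints by the configured
#' positional model (truncated to the reference window), and emits the two
#' mate records per fragment as already-aligned SAM-style records: correct
#' 1-based starts on the window's contig, all-match CIGARs, proper-pair
#' FLAG bits (99/147), i.i.d. substitution errors at \code{error_rate}, and
#' MAPQ \code{mapq_value} except for a \code{frac_low_mapq} subset of reads
#' assigned \code{low_mapq_value}. Deterministic given the config seed.
#'
#' Fragments that would be shorter than the read length or would overflow
#' the window are resampled (the count is returned in
#' \code{n_resampled}).
#'
#' @param genotype A \code{\link{clone_genotype}}.
#' @param config An \code{\link{atac_sim_config}}.
#' @return List with \code{reads} (data.frame of SAM fields, two rows per
#'   fragment), \code{truth} (per-fragment ground truth: fragment_id,
#'   haplotype, start, end) and \code{n_resampled}.
#' @export
simulate_clone_reads <- function(genotype, config) {
  stopifnot(inherits(genotype, "clone_genotype"),
            inherits(config, "atac_sim_config"))
  w <- config$reference_window
  n <- config$n_fragments
  rl <- config$read_length
  win_end <- window_end(w)

  hap_seqs <- vapply(genotype$haplotype_pair, haplotype_sequence,
                     character(1), window = w)
  weights <- vapply(genotype$haplotype_pair,
                    function(h) h$accessibility_weight, numeric(1))
  if (sum(weights) <= 0)
    stop("haplotype weights sum to zero", call. = FALSE)
  labels <- vapply(genotype$haplotype_pair, function(h) h$label, character(1))

  edit_pos <- unique(unlist(lapply(genotype$haplotype_pair,
                                   function(h) h$edits$position)))
  if (length(edit_pos) &&
      (any(edit_pos - w$start < rl) || any(window_end(w) - edit_pos < rl)))
    stop("edit positions need >= read_length flanks inside the window",
         call. = FALSE)

  with_seed(config$seed, {
    hap_idx <- sample.int(2L, n, replace = TRUE, prob = weights / sum(weights))

    # Rejection-sample fragment (length, midpoint) pairs until each fragment
    # fits inside the window with length >= read_length.
    len <- integer(n); start <- integer(n)
    todo <- seq_len(n); n_resampled <- 0L; tries <- 0L
    while (length(todo)) {
      m <- length(todo)
      l <- as.integer(round(rnorm(m, config$fragment_length_mean,
                                  config$fragment_length_sd)))
      mid <- if (config$position_model == "gaussian")
        rnorm(m, config$peak_center, config$peak_sd)
      else
        runif(m, w$start, win_end)
      s <- as.integer(round(mid - l / 2))
      ok <- l >= rl & s >= w$start & (s + l - 1L) <= win_end
      len[todo[ok]] <- l[ok]
      start[todo[ok]] <- s[ok]
      n_resampled <- n_resampled + sum(!ok)
      todo <- todo[!ok]
      tries <- tries + 1L
      if (tries > 1000L)
        stop("window overflow: cannot place fragments inside the window",
             call. = FALSE)
    }
    end <- start + len - 1L

    # Mate sequences are substrings of the source haplotype, recorded in
    # reference orientation as SAM stores them.
    loc1 <- start - w$start + 1L
    loc2 <- end - rl + 1L - w$start + 1L
    seq1 <- substring(hap_seqs[hap_idx], loc1, loc1 + rl - 1L)
    seq2 <- substring(hap_seqs[hap_idx], loc2, loc2 + rl - 1L)

    qname <- sprintf("%s_f%06d", genotype$clone_id, seq_len(n))
    qual0 <- strrep(PHRED_HIGH, rl)

    reads <- data.frame(
      qname = rep(qname, 2L),
      flag  = rep(c(99L, 147L), each = n),
      rname = w$contig,
      pos   = c(start, end - rl + 1L),
      mapq  = config$mapq_value,
      cigar = paste0(rl, "M"),
      rnext = "=",
      pnext = c(end - rl + 1L, start),
      tlen  = c(len, -len),
      seq   = c(seq1, seq2),
      qual  = qual0,
      stringsAsFactors = FALSE)

    # i.i.d. substitution errors; erroneous bases get low base quality.
    if (config$error_rate > 0) {
      nb <- nrow(reads) * rl
      hit <- which(runif(nb) < config$error_rate)
      if (length(hit)) {
        ri <- ((hit - 1L) %/% rl) + 1L
        bi <- ((hit - 1L) %% rl) + 1L
        for (k in seq_along(hit)) {
          old <- substr(reads$seq[ri[k]], bi[k], bi[k])
          new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          substr(reads$seq[ri[k]], bi[k], bi[k]) <- new
          substr(reads$qual[ri[k]], bi[k], bi[k]) <- PHRED_ERR
        }
      }
    }

    if (config$frac_low_mapq > 0) {
      low <- runif(nrow(reads)) < config$frac_low_mapq
      reads$mapq[low] <- config$low_mapq_value
    }

    truth <- data.frame(fragment_id = qname,
                        haplotype = labels[hap_idx],
                        start = start, end = end,
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth, n_resampled = n_resampled)
  })
}

#' Simulation configuration for grouped phenotype tables
#'
#' Generator for the numeric group-comparison fixtures consumed by the
#' statistical decision engine: independent groups drawn from normal or
#' lognormal distributions, optionally with a nested subject level
#' (subjects per group with replicate measurements and a subject-level
#' random intercept). For the lognormal case \code{group_means} are
#' geometric means and \code{group_sds} are log-scale standard deviations,
#' so the log2 transform restores normality by construction.
#'
#' @param n_groups Number of groups.
#' @param n_per_group Observations per group (ignored in nested mode).
#' @param distribution \code{"normal"} or \code{"lognormal"}.
#' @param group_means,group_sds Length-\code{n_groups} (or scalar) location
#'   and scale per group; sds must be positive.
#' @param nested Optional list with \code{subjects_per_group},
#'   \code{replicates_per_subject} and \code{subject_sd}.
#' @param seed Integer seed.
#' @return An object of class \code{pheno_sim_config}.
#' @export
pheno_sim_config <- function(n_groups = 2L, n_per_group = 8L,
                             distribution = c("normal", "lognormal"),
                             group_means = 0, group_sds = 1,
                             nested = NULL, seed = 1L) {
  distribution <- match.arg(distribution)
  group_means <- rep_len(group_means, n_groups)
  group_sds <- rep_len(group_sds, n_groups)
  if (any(group_sds <= 0)) stop("group sds must be positive", call. = FALSE)
  if (is.null(nested) && n_per_group < 3L)
    stop("n_per_group must be at least 3", call. = FALSE)
  if (!is.null(nested)) {
    stopifnot(all(c("subjects_per_group", "replicates_per_subject",
                    "subject_sd") %in% names(nested)))
    if (nested$subjects_per_group < 2L)
      stop("nested mode needs at least 2 subjects per group", call. = FALSE)
  }
  structure(list(n_groups = as.integer(n_groups),
                 n_per_group = as.integer(n_per_group),
                 distribution = distribution,
                 group_means = group_means, group_sds = group_sds,
                 nested = nested, seed = as.integer(seed)),
            class = "pheno_sim_config")
}

#' Simulate a grouped phenotype table
#'
#' @param config A \code{\link{pheno_sim_config}}.
#' @return data.frame with columns \code{group}, \code{value} and, in nested
#'   mode, \code{subject}.
#' @export
simulate_grouped_phenotypes <- function(config) {
  stopifnot(inherits(config, "pheno_sim_config"))
  with_seed(config$seed, {
    if (is.null(config$nested)) {
      g <- rep(paste0("g", seq_len(config$n_groups)),
               each = config$n_per_group)
      mu <- rep(config$group_means, each = config$n_per_group)
      sd <- rep(config$group_sds, each = config$n_per_group)
      val <- if (config$distribution == "normal")
        rnorm(length(g), mu, sd)
      else
        exp(rnorm(length(g), log(mu), sd))
      data.frame(group = g, value = val, stringsAsFactors = FALSE)
    } else {
      ns <- config$nested$subjects_per_group
      nr <- config$nested$replicates_per_subject
      rows <- expand.grid(rep = seq_len(nr), subj = seq_len(ns),
                          grp = seq_len(config$n_groups))
      subj_id <- paste0("g", rows$grp, "_s", rows$subj)
      intercepts <- rnorm(config$n_groups * ns, 0, config$nested$subject_sd)
      names(intercepts) <- unique(paste0(
        "g", rep(seq_len(config$n_groups), each = ns), "_s",
        rep(seq_len(ns), config$n_groups)))
      mu <- config$group_means[rows$grp] + intercepts[subj_id]
      sd <- config$group_sds[rows$grp]
      val <- if (config$distribution == "normal")
        rnorm(nrow(rows), mu, sd)
      else
        exp(rnorm(nrow(rows), log(mu), sd))
      data.frame(group = paste0("g", rows$grp), subject = subj_id,
                 value = val, stringsAsFactors = FALSE)
    }
  })
}
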