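# Shared fixtures and independent oracles for the test suite.

scheme <- edit_scheme()

# Reference window reused across tests (deterministic).
test_window <- build_reference_window(seed = 99L)

# One clone's ratio from a fresh simulation (read-unit counting).
sim_clone_ratio <- function(n_fragments, weight, group, seed,
                            window = test_window, error_rate = 0) {
  geno <- clone_genotype("c", group, scheme, weights = c(1, weight))
  cfg <- atac_sim_config(window, n_fragments = n_fragments,
                         error_rate = error_rate, seed = seed)
  sim <- simulate_clone_reads(geno, cfg)
  counts <- count_alleles(sim$reads, scheme, clone_id = "c")
  allelic_ratio(counts, group)
}

# Build a single alignment record as a one-row data.frame.
make_read <- function(pos, cigar, seq, qual = strrep("F", nchar(seq)),
                      qname = "r", flag = 0L, mapq = 42L,
                      rname = "chr19") {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = "*", pnext = 0L,
             tlen = 0L, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

# A 75M read spanning both edited sites, with chosen bases at the two
# loci (offsets inside the read computed from the start position).
site_read <- function(pam_base, var_base, pos = 50739280L,
                      pam_qual_char = "F", var_qual_char = "F",
                      cigar = "75M", fill = "A", qname = "r",
                      flag = 0L, mapq = 42L) {
  len <- 75L
  seq <- strrep(fill, len)
  qual <- strrep("F", len)
  i_pam <- scheme$pam_pos - pos + 1L
  i_var <- scheme$var_pos - pos + 1L
  if (i_pam >= 1 && i_pam <= len) {
    substr(seq, i_pam, i_pam) <- pam_base
    substr(qual, i_pam, i_pam) <- pam_qual_char
  }
  if (i_var >= 1 && i_var <= len) {
    substr(seq, i_var, i_var) <- var_base
    substr(qual, i_var, i_var) <- var_qual_char
  }
  make_read(pos, cigar, seq, qual, qname = qname, flag = flag, mapq = mapq)
}

# Independent oracle for base_at: expand the full reference<->query map
# base by base (no shared code with the package's CIGAR walk).
oracle_base_at <- function(pos, cigar, seq, position) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  ref <- pos; q <- 1L
  map <- character(0)
  for (tok in toks) {
    len <- as.integer(sub("[A-Z=]$", "", tok))
    op <- sub("^[0-9]+", "", tok)
    if (op %in% c("M", "=", "X")) {
      for (k in 0:(len - 1L))
        map[as.character(ref + k)] <- substr(seq, q + k, q + k)
      ref <- ref + len; q <- q + len
    } else if (op %in% c("D", "N")) {
      for (k in 0:(len - 1L)) map[as.character(ref + k)] <- "DELETED"
      ref <- ref + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    }
  }
  out <- map[as.character(position)]
  if (is.na(out)) "NOT_COVERED" else unname(out)
}

# Random valid CIGAR with matching sequence, for property tests.
random_cigar_read <- function(pos = 1000L) {
  n_ops <- sample(1:5, 1)
  ops <- character(0); lens <- integer(0)
  ops <- c(ops, "M"); lens <- c(lens, sample(5:30, 1))
  if (n_ops > 1) {
    for (k in seq_len(n_ops - 1L)) {
      ops <- c(ops, sample(c("M", "I", "D", "S"), 1))
      lens <- c(lens, sample(1:15, 1))
    }
  }
  # soft clips only at the ends; collapse interior S into M
  if (length(ops) > 2)
    ops[2:(length(ops) - 1L)][ops[2:(length(ops) - 1L)] == "S"] <- "M"
  qlen <- sum(lens[ops %in% c("M", "I", "S")])
  seq <- paste(sample(c("A", "C", "G", "T"), qlen, TRUE), collapse = "")
  make_read(pos, paste0(lens, ops, collapse = ""), seq,
            qual = strrep("F", qlen))
}
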