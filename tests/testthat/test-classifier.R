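# Dual-locus read classification and per-clone tallies.

# Hand-written truth table for the informative base combinations, written
# out independently of the implementation: (C,G) wild-type, (G,G)
# control-edited, (G,A) variant, (C,A) variant-without-PAM, anything else
# unexpected.
truth_table <- local({
  bases <- c("A", "C", "G", "T")
  tab <- expand.grid(pam = bases, var = bases, stringsAsFactors = FALSE)
  tab$category <- "UNINFORMATIVE"
  tab$reason <- "unexpected_base"
  set <- function(tab, p, v, cat, rea = NA_character_) {
    i <- tab$pam == p & tab$var == v
    tab$category[i] <- cat; tab$reason[i] <- rea
    tab
  }
  tab <- set(tab, "C", "G", "WT")
  tab <- set(tab, "G", "G", "CONTROL_EDITED")
  tab <- set(tab, "G", "A", "VARIANT")
  tab <- set(tab, "C", "A", "UNINFORMATIVE", "variant_without_pam")
  tab
})

test_that("classify_read matches the exhaustive truth table", {
  # 16 base combinations x {high, low} base quality, plus coverage and
  # deletion cases: > 32 states, each checked exactly.
  for (i in seq_len(nrow(truth_table))) {
    tt <- truth_table[i, ]
    call <- classify_read(site_read(tt$pam, tt$var), scheme,
                          min_base_quality = 20)
    expect_identical(call$category, tt$category,
                     label = sprintf("(%s,%s) category", tt$pam, tt$var))
    expect_identical(call$reason, tt$reason,
                     label = sprintf("(%s,%s) reason", tt$pam, tt$var))

    # same combination with a low-quality base at the PAM site ("+" = Q10)
    low <- classify_read(site_read(tt$pam, tt$var, pam_qual_char = "+"),
                         scheme, min_base_quality = 20)
    expect_identical(low$category, "UNINFORMATIVE")
    expect_identical(low$reason, "low_base_quality")
  }

  # coverage: a read covering the PAM but ending before the variant site
  ns <- classify_read(make_read(50739260L, "40M", strrep("A", 40)), scheme)
  expect_identical(ns$reason, "not_spanning")
  # and one starting after the PAM
  ns2 <- classify_read(site_read("C", "G", pos = 50739300L), scheme)
  expect_identical(ns2$reason, "not_spanning")
  # deletion overlapping the PAM site
  del <- classify_read(
    make_read(50739280L, "5M10D60M", strrep("C", 65)), scheme)
  expect_identical(del$reason, "deletion_at_site")
  # base-quality rule disabled at threshold 0 reproduces the literal rule
  lowq <- classify_read(site_read("C", "G", pam_qual_char = "+"), scheme,
                        min_base_quality = 0)
  expect_identical(lowq$category, "WT")
})

test_that("a read spanning one site only is uninformative by span arithmetic", {
  # 75M starting at 50739260 spans 50739260..50739334: PAM covered,
  # variant (50739310) also covered -- so place the read to exclude it.
  r <- site_read("C", "G", pos = 50739260L)
  expect_identical(classify_read(r, scheme)$category, "WT")
  r2 <- site_read("C", "G", pos = 50739235L)  # span ends at 50739309
  expect_identical(classify_read(r2, scheme)$reason, "not_spanning")
  r3 <- site_read("C", "G", pos = 50739236L)  # span ends exactly at the site
  expect_identical(classify_read(r3, scheme)$category, "WT")
})

test_that("count_alleles tallies a hand-built six-record SAM correctly", {
  reads <- rbind(
    site_read("C", "G", qname = "wt"),
    site_read("G", "G", qname = "ce"),
    site_read("G", "A", qname = "va"),
    site_read("C", "A", qname = "vwp"),
    make_read(50739260L, "40M", strrep("A", 40), qname = "ns"),
    site_read("T", "G", qname = "ux"))
  counts <- count_alleles(reads, scheme, clone_id = "six")
  expect_identical(counts$n_wt, 1L)
  expect_identical(counts$n_control_edited, 1L)
  expect_identical(counts$n_variant, 1L)
  expect_identical(counts$n_total_informative, 3L)
  expect_identical(counts$n_uninformative, 3L)
  r <- counts$n_uninformative_by_reason
  expect_identical(r[["variant_without_pam"]], 1L)
  expect_identical(r[["not_spanning"]], 1L)
  expect_identical(r[["unexpected_base"]], 1L)
  # conservation: all six records accounted for
  expect_identical(counts$n_total_informative + counts$n_uninformative +
                     counts$n_excluded, 6L)
  # TSV projection carries the full reason histogram
  tab <- as.data.frame(counts)
  expect_identical(tab$n_variant_without_pam, 1L)
})

test_that("classification is invariant to read order and strand", {
  geno <- clone_genotype("c", "het_variant", scheme)
  cfg <- atac_sim_config(test_window, n_fragments = 400, seed = 9)
  sim <- simulate_clone_reads(geno, cfg)
  c1 <- count_alleles(sim$reads, scheme, clone_id = "c")
  shuffled <- sim$reads[sample(nrow(sim$reads)), ]
  c2 <- count_alleles(shuffled, scheme, clone_id = "c")
  expect_identical(c1[c("n_wt", "n_control_edited", "n_variant")],
                   c2[c("n_wt", "n_control_edited", "n_variant")])
  flipped <- sim$reads
  flipped$flag <- bitwXor(flipped$flag, 0x10L)
  c3 <- count_alleles(flipped, scheme, clone_id = "c")
  expect_identical(c1[c("n_wt", "n_control_edited", "n_variant")],
                   c3[c("n_wt", "n_control_edited", "n_variant")])
})

test_that("error-free classifier fractions equal the simulator's spanning-fragment truth", {
  geno <- clone_genotype("c", "het_variant", scheme, weights = c(1, 0.7))
  cfg <- atac_sim_config(test_window, n_fragments = 3000, error_rate = 0,
                         seed = 41)
  sim <- simulate_clone_reads(geno, cfg)
  counts <- count_alleles(sim$reads, scheme, clone_id = "c")
  # truth restricted to reads that span both sites
  pam <- atacAllele:::bases_at(sim$reads$pos, sim$reads$cigar,
                               sim$reads$seq, sim$reads$qual, 50739290L)
  var <- atacAllele:::bases_at(sim$reads$pos, sim$reads$cigar,
                               sim$reads$seq, sim$reads$qual, 50739310L)
  spanning <- pam$base %in% c("A", "C", "G", "T") &
    var$base %in% c("A", "C", "G", "T")
  hap <- setNames(sim$truth$haplotype, sim$truth$fragment_id)
  span_hap <- hap[sim$reads$qname[spanning]]
  expect_identical(counts$n_variant,
                   sum(unname(span_hap) == "PAM_PLUS_VARIANT"))
  expect_identical(counts$n_wt, sum(unname(span_hap) == "WT"))
  expect_identical(counts$n_control_edited, 0L)
})

test_that("homozygous clones yield a single informative category", {
  geno <- clone_genotype("c", "hom_variant", scheme)
  cfg <- atac_sim_config(test_window, n_fragments = 500, error_rate = 0,
                         seed = 6)
  sim <- simulate_clone_reads(geno, cfg)
  counts <- count_alleles(sim$reads, scheme, clone_id = "c")
  expect_identical(counts$n_wt, 0L)
  expect_identical(counts$n_control_edited, 0L)
  expect_gt(counts$n_variant, 0L)
  # every spanning read carries both edits
  expect_identical(counts$n_uninformative,
                   counts$n_uninformative_by_reason[["not_spanning"]])
})

test_that("fragment mode merges mates and flags discordance", {
  concordant <- rbind(site_read("G", "A", qname = "f1", flag = 99L),
                      site_read("G", "A", qname = "f1", flag = 147L))
  one_informative <- rbind(site_read("C", "G", qname = "f2", flag = 99L),
                           make_read(50739260L, "40M", strrep("A", 40),
                                     qname = "f2", flag = 147L))
  discordant <- rbind(site_read("C", "G", qname = "f3", flag = 99L),
                      site_read("G", "A", qname = "f3", flag = 147L))
  counts <- count_alleles(rbind(concordant, one_informative, discordant),
                          scheme, unit = "fragment", clone_id = "m")
  expect_identical(counts$n_variant, 1L)  # f1 counted once
  expect_identical(counts$n_wt, 1L)       # f2 takes the informative mate
  expect_identical(counts$n_uninformative_by_reason[["unexpected_base"]], 1L)
  expect_identical(counts$n_total_informative, 2L)
})

test_that("MAPQ and duplicate handling inside count_alleles", {
  r_low <- site_read("C", "G", qname = "low", mapq = 5L)
  r_ok <- site_read("C", "G", qname = "ok")
  r_dup <- site_read("C", "G", qname = "dup", flag = 0x400L)
  r_sec <- site_read("C", "G", qname = "sec", flag = 0x100L)
  counts <- count_alleles(rbind(r_low, r_ok, r_dup, r_sec), scheme,
                          clone_id = "c")
  expect_identical(counts$n_wt, 2L)  # duplicates retained by default
  expect_identical(counts$n_uninformative_by_reason[["low_mapq"]], 1L)
  expect_identical(counts$n_excluded, 1L)  # the secondary record
  dd <- count_alleles(rbind(r_low, r_ok, r_dup, r_sec), scheme,
                      dedup = TRUE, clone_id = "c")
  expect_identical(dd$n_wt, 1L)
  expect_warning(count_alleles(empty <- r_ok[0, ], scheme), "no input")
})

test_that("genotype_amplicon classifies the printed donor oligos and het proxies", {
  expect_identical(genotype_amplicon(ssodn_control(), scheme, 50739240L),
                   "hom_control")
  expect_identical(genotype_amplicon(ssodn_variant(), scheme, 50739240L),
                   "hom_variant")
  expect_identical(genotype_amplicon(ssodn_reference(), scheme, 50739240L),
                   "wild_type")
  # IUPAC double-peak proxies: S = C/G at the PAM, R = G/A at the variant
  het_c <- ssodn_reference(); substr(het_c, 51, 51) <- "S"
  expect_identical(genotype_amplicon(het_c, scheme, 50739240L),
                   "het_control")
  het_v <- het_c; substr(het_v, 71, 71) <- "R"
  expect_identical(genotype_amplicon(het_v, scheme, 50739240L),
                   "het_variant")
  odd <- ssodn_reference(); substr(odd, 51, 51) <- "T"
  expect_identical(genotype_amplicon(odd, scheme, 50739240L), "ambiguous")
  expect_error(genotype_amplicon("ACGT", scheme, 50739240L), "cover")
})
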