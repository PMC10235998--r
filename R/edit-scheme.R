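#' Define the dual-locus CRISPR edit scheme
#'
#' An edit scheme records the two engineered genomic positions that tag the
#' alleles of an HDR-edited clone: a PAM-blocking mutation (a silent edit
#' that destroys the NGG protospacer-adjacent motif so Cas9 cannot re-cut
#' the repaired allele, and which doubles as the tag for "control-edited"
#' reads) and the candidate regulatory variant itself. The defaults encode
#' the rs182722517 locus: a C>G PAM edit at chr19:50739290 and the G>A
#' variant at chr19:50739310 (GRCh38), 20 bp apart inside the
#' chr19:50739241-50739456 candidate cis-regulatory element.
#'
#' @param contig Reference sequence name.
#' @param pam_pos,pam_ref,pam_alt 1-based position and ref/alt base of the
#'   PAM-blocking edit.
#' @param var_pos,var_ref,var_alt 1-based position and ref/alt base of the
#'   variant site.
#' @return An object of class \code{edit_scheme}.
#' @examples
#' edit_scheme()
#' @export
edit_scheme <- function(contig = "chr19",
                        pam_pos = 50739290L, pam_ref = "C", pam_alt = "G",
                        var_pos = 50739310L, var_ref = "G", var_alt = "A") {
  bases <- c(pam_ref, pam_alt, var_ref, var_alt)
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("ref/alt bases must be one of A, C, G, T", call. = FALSE)
  if (pam_pos == var_pos)
    stop("PAM and variant positions must differ", call. = FALSE)
  if (pam_ref == pam_alt || var_ref == var_alt)
    stop("ref and alt base must differ at each site", call. = FALSE)
  structure(list(contig = contig,
                 pam_pos = as.integer(pam_pos), pam_ref = pam_ref,
                 pam_alt = pam_alt,
                 var_pos = as.integer(var_pos), var_ref = var_ref,
                 var_alt = var_alt),
            class = "edit_scheme")
}

#' @export
print.edit_scheme <- function(x, ...) {
  cat("Dual-locus edit scheme on", x$contig, "\n")
  cat(sprintf("  PAM site:     %s:%d %s>%s\n", x$contig, x$pam_pos,
              x$pam_ref, x$pam_alt))
  cat(sprintf("  variant site: %s:%d %s>%s\n", x$contig, x$var_pos,
              x$var_ref, x$var_alt))
  invisible(x)
}

#' Printed HDR donor (ssODN) sequences for the rs182722517 edit
#'
#' The two 121-nt single-stranded oligodeoxynucleotide donor templates used
#' to engineer the clones: the control donor carries only the C>G
#' PAM-blocking mutation, the variant donor additionally carries the G>A
#' substitution at the variant site. \code{ssodn_reference()} returns the
#' pre-edit genomic context, i.e. the control donor with the PAM base
#' reverted to the reference C; the PAM base sits at position 51 of the
#' oligo and the variant base at position 71.
#'
#' @return A single nucleotide string.
#' @export
ssodn_control <- function() {
  paste0("TCACGTTCTCCTCCACCATAGCACAGAGCGTCTAAGGGTGCCACCCTCTCG",
         "CATAACTAGAGACACATGAGTGACAGCAGCAATGAGCTGTCCCATCTGCTAGTCGTCGACACAGAAGAGC")
}

#' @rdname ssodn_control
#' @export
ssodn_variant <- function() {
  paste0("TCACGTTCTCCTCCACCATAGCACAGAGCGTCTAAGGGTGCCACCCTCTCG",
         "CATAACTAGAGACACATGAATGACAGCAGCAATGAGCTGTCCCATCTGCTAGTCGTCGACACAGAAGAGC")
}

#' @rdname ssodn_control
#' @export
ssodn_reference <- function() {
  x <- ssodn_control()
  substr(x, 51L, 51L) <- "C"   # revert the PAM-blocking edit
  x
}

# Offset of the PAM base within the printed ssODN (1-based).
SSODN_PAM_OFFSET <- 51L
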