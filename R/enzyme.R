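#' Define the cut geometry of a methylation-dependent restriction enzyme
#'
#' An `enzyme_spec` bundles the recognition motif and the cut geometry of a
#' methylation-dependent endonuclease of the MspJI family. The enzyme binds a
#' motif anchored on a methylated cytosine (for MspJI, `mCNNR`) and cleaves
#' both strands downstream of the motif: the strand carrying the motif is cut
#' `cut_near` bp from the methylated C and the opposite strand `cut_far` bp
#' away, leaving a 5' overhang of `cut_far - cut_near` nt. After adapter
#' ligation, the 5' end of a read from the motif-distal side of the cut
#' starts `countable_offset` bp past the motif's far edge; this offset is
#' what anchors read counting to motif sites.
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition motif, anchored on the methylated
#'   cytosine (first symbol must be compatible with `C`).
#' @param analysis_pattern IUPAC subset of the recognition motif used for
#'   read counting. MspJI cuts at `CNNR`, but analysis is usually restricted
#'   to the CpG-context subset `CGNR` because canonical mammalian methylation
#'   is at CpG.
#' @param cut_near Distance in bp from the methylated C to the scission on
#'   the motif-proximal strand (13 for MspJI).
#' @param cut_far Distance in bp to the scission on the opposite strand
#'   (17 for MspJI).
#' @param overhang Length in nt of the 5' overhang left by digestion
#'   (`cut_far - cut_near`).
#' @param countable_offset Expected distance in bp from the motif's near edge
#'   to the 5' start of a countable read (`cut_near - (motif length - 1)`;
#'   10 for the 4-bp MspJI motif).
#'
#' @return An object of class `enzyme_spec`.
#' @examples
#' mspji()
#' enzyme_spec("MspJI-CG-only", recognition = "CGNR", analysis_pattern = "CGNR")
#' @export
enzyme_spec <- function(name = "MspJI",
                        recognition = "CNNR",
                        analysis_pattern = "CGNR",
                        cut_near = 13L,
                        cut_far = 17L,
                        overhang = 4L,
                        countable_offset = 10L) {
  recognition <- toupper(recognition)
  analysis_pattern <- toupper(analysis_pattern)
  check_iupac(recognition)
  check_iupac(analysis_pattern)
  cut_near <- as.integer(cut_near)
  cut_far <- as.integer(cut_far)
  overhang <- as.integer(overhang)
  countable_offset <- as.integer(countable_offset)
  if (substr(recognition, 1L, 1L) != "C")
    stop("recognition motif must be anchored on the methylated C (first symbol 'C')")
  if (cut_far - cut_near != overhang)
    stop("cut_far - cut_near must equal the overhang length")
  if (countable_offset != cut_near - (nchar(recognition) - 1L))
    stop("countable_offset must equal cut_near - (motif length - 1)")
  if (nchar(analysis_pattern) != nchar(recognition))
    stop("analysis_pattern must have the same length as the recognition motif")
  structure(
    list(name = name,
         recognition = recognition,
         analysis_pattern = analysis_pattern,
         cut_near = cut_near,
         cut_far = cut_far,
         overhang = overhang,
         countable_offset = countable_offset),
    class = "enzyme_spec"
  )
}

#' @describeIn enzyme_spec The default MspJI specification: recognizes
#'   `mCNNR`, cuts 13 and 17 bp from the methylated C, leaves a 4-nt 5'
#'   overhang; analysis restricted to `CGNR`.
#' @export
mspji <- function() enzyme_spec()

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s\n", x$name))
  cat(sprintf("  recognition: %s (analysis: %s)\n", x$recognition, x$analysis_pattern))
  cat(sprintf("  cuts at %d/%d bp from mC; 5' overhang %d nt; countable offset %d bp\n",
              x$cut_near, x$cut_far, x$overhang, x$countable_offset))
  invisible(x)
}

# IUPAC nucleotide codes; N deliberately matches only A/C/G/T here, so an N
# in the reference never satisfies a motif.
check_iupac <- function(pattern) {
  ok <- strsplit(pattern, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok))
    stop("invalid IUPAC symbol(s) in pattern: ",
         paste(unique(strsplit(pattern, "")[[1]][!ok]), collapse = ", "))
  invisible(TRUE)
}

reverse_complement_pattern <- function(pattern) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
}
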