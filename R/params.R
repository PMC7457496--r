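#' Default analysis parameters
#'
#' Central registry of the pipeline defaults: read-mapping costs and
#' acceptance fractions (default and strict remapping stringencies), the
#' coverage screening threshold, dispersed-repeat search settings, and the
#' MISA-style microsatellite thresholds.  Subcommands of [plastid_main()] and
#' the individual analysis functions all draw their defaults from here, so a
#' single place documents the numbers a run is reproduced with.
#'
#' @return Named list of parameter groups:
#' \describe{
#'   \item{mapping}{mismatch/insertion/deletion costs, default and strict
#'     (length fraction, similarity fraction) pairs, seed length.}
#'   \item{coverage}{minimum acceptable per-base depth (40).}
#'   \item{repeats}{minimum repeat length 30 nt, maximum Hamming distance 3.}
#'   \item{ssr}{minimum repeat counts per unit size (mono 10, di 6, tri 5,
#'     tetra/penta/hexa 3) and the 100 nt compound-merge distance.}
#'   \item{junction}{overlap search bounds and the 19-51 nt diagnostic range.}
#'   \item{ir}{inverted-repeat detection seed and minimum length.}
#' }
#' @export
#' @examples
#' default_params()$ssr$min_repeats
default_params <- function() {
  list(
    mapping = list(
      mismatch_cost = 2L, insertion_cost = 3L, deletion_cost = 3L,
      length_fraction = 0.8, similarity_fraction = 0.9,
      strict_length_fraction = 0.99, strict_similarity_fraction = 0.99,
      seed_length = 21L
    ),
    coverage = list(min_depth = 40L),
    repeats = list(min_length = 30L, max_hamming = 3L,
                   kinds = c("forward", "reverse", "complement", "palindromic"),
                   exclude_ir_duplicate = TRUE),
    ssr = list(min_repeats = c(10L, 6L, 5L, 3L, 3L, 3L),
               compound_max_gap = 100L),
    junction = list(min_overlap = 15L, max_overlap = 200L, max_mismatches = 0L,
                    expected_range = c(19L, 51L), gap_flank = 300L),
    ir = list(min_ir_length = 1000L, seed_length = 31L,
              max_mismatch_fraction = 0.001)
  )
}
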