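#' Genome model for an average HeLa Kyoto cell
#'
#' HeLa Kyoto is hypotriploid with a mean genome size of 7.9 Gb over
#' ~64 chromosomes. During mitosis the genome is replicated, so a cell
#' carries 2 x 7.9 Gb distributed over 128 sister chromatids; the
#' average chromatid then holds `genome_size / n_chromosomes` =
#' 123.4 Mb.
#'
#' @param genome_size_bp haploid-equivalent genome size (default 7.9e9)
#' @param n_chromosomes chromosome count (default 64)
#' @return a `genome_model`: `genome_size_bp`, `n_chromosomes`,
#'   `n_chromatids`, `total_bp` (replicated), `chromatid_bp`
#' @export
genome_model <- function(genome_size_bp = 7.9e9, n_chromosomes = 64L) {
  stopifnot(genome_size_bp > 0, n_chromosomes > 0)
  structure(list(genome_size_bp = genome_size_bp,
                 n_chromosomes = n_chromosomes,
                 n_chromatids = 2L * n_chromosomes,
                 total_bp = 2 * genome_size_bp,
                 chromatid_bp = genome_size_bp / n_chromosomes),
            class = "genome_model")
}

#' Chromosome-bound Condensin subunit census per mitotic phase
#'
#' Loads the packaged census of chromosome-bound subunit copy numbers
#' (means and SDs per replicated genome) and total chromatid-axis
#' lengths for late prometaphase, metaphase and early anaphase, or any
#' CSV with the same columns.
#'
#' @param path optional CSV path; default is the packaged census
#' @return data frame, one row per phase
#' @export
condensin_census <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "condensin_census.csv",
                        package = "condensinmap")
  census <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("phase", "total_axis_length_um", "SMC4", "CAP_D2", "CAP_H",
              "CAP_D3", "CAP_H2")
  stopifnot(all(needed %in% names(census)))
  census
}

SUBUNITS <- c("SMC4", "CAP_D2", "CAP_H", "CAP_D3", "CAP_H2")

#' Genomic and physical Condensin spacing table for one mitotic phase
#'
#' Converts the whole-cell census into the derived per-phase
#' quantities: per-chromatid, per-um-axis and per-Mb subunit counts,
#' the mean genomic spacing `total_bp / N` (equidistant-spacing
#' assumption along chromatid arms), the mean physical spacing
#' `axis_length / N`, the axis length constraining 1 Mb of DNA, the
#' combined kleisin pool (CAP-H + CAP-H2, an upper bound on
#' holocomplexes since the kleisin closes the ring), and the implied
#' maximal loop sizes under the loop-extrusion assumption of one
#' holocomplex per fully extruded loop: the Condensin II loop size is
#' the CAP-H2 genomic spacing and the combined (sub)loop size the
#' combined-kleisin genomic spacing.
#'
#' @param census one-row data frame (or list) with subunit totals and
#'   `total_axis_length_um` (see [condensin_census()])
#' @param genome a [genome_model()]
#' @return a `loop_table` with per-subunit vectors (`totals`,
#'   `per_chromatid`, `per_um_axis`, `per_Mb`, `genomic_spacing_kb`,
#'   `physical_spacing_nm`) and scalars `nm_per_Mb`, `Mb_per_um`,
#'   `combined_kleisin_total`, `loop_size_CII_kb`,
#'   `loop_size_combined_kb`, `ratio_I_to_II`,
#'   `predicted_axial_spacing_CII_nm`
#' @export
build_loop_table <- function(census, genome = genome_model()) {
  census <- as.list(census)
  totals <- vapply(SUBUNITS, function(s) as.numeric(census[[s]]), numeric(1))
  if (any(!is.finite(totals)) || any(totals <= 0))
    stop("census totals must be positive for all subunits")
  axis_um <- as.numeric(census$total_axis_length_um)
  stopifnot(axis_um > 0)
  axis_nm <- axis_um * 1000
  total_bp <- genome$total_bp
  total_Mb <- total_bp / 1e6

  combined <- totals[["CAP_H"]] + totals[["CAP_H2"]]
  tot_ext <- c(totals, CAP_H_plus_CAP_H2 = combined)
  structure(list(
    phase = census$phase %||% NA_character_,
    totals = tot_ext,
    total_axis_length_um = axis_um,
    per_chromatid = tot_ext / genome$n_chromatids,
    per_um_axis = tot_ext / axis_um,
    per_Mb = tot_ext / total_Mb,
    genomic_spacing_kb = total_bp / tot_ext / 1000,
    physical_spacing_nm = axis_nm / tot_ext,
    nm_per_Mb = axis_nm / total_Mb,
    Mb_per_um = total_Mb / axis_um,
    chromatid_length_um = axis_um / genome$n_chromatids,
    chromatid_Mb = genome$chromatid_bp / 1e6,
    combined_kleisin_total = combined,
    loop_size_CII_kb = total_bp / totals[["CAP_H2"]] / 1000,
    loop_size_combined_kb = total_bp / combined / 1000,
    ratio_I_to_II = totals[["CAP_H"]] / totals[["CAP_H2"]],
    predicted_axial_spacing_CII_nm = axis_nm / totals[["CAP_H2"]]),
    class = "loop_table")
}

#' @export
print.loop_table <- function(x, ...) {
  cat(sprintf("<loop_table> phase: %s, axis %.1f um\n", x$phase,
              x$total_axis_length_um))
  m <- rbind(total = sprintf("%d", round(x$totals)),
             per_chromatid = sprintf("%d", round(x$per_chromatid)),
             per_um = sprintf("%d", round(x$per_um_axis)),
             per_Mb = sprintf("%d", round(x$per_Mb)),
             genomic_kb = sprintf("%.1f", x$genomic_spacing_kb),
             physical_nm = sprintf("%.1f", x$physical_spacing_nm))
  colnames(m) <- names(x$totals)
  print(m, quote = FALSE)
  cat(sprintf("1 Mb == %.1f nm axis; CII loop %.1f kb; combined loop %.1f kb; I:II %.2f\n",
              x$nm_per_Mb, x$loop_size_CII_kb, x$loop_size_combined_kb,
              x$ratio_I_to_II))
  invisible(x)
}

#' Kleisin-limited holocomplex count and fraction
#'
#' The kleisin closes the pentameric ring, so the number of complete
#' holocomplexes is bounded by the smaller of the kleisin and
#' HEAT-repeat subunit pools; the fraction of HEAT subunits that can be
#' incorporated is `kleisin / heat`.
#'
#' @param kleisin_total,heat_total chromosome-bound copy numbers (>= 0)
#' @return list with `holocomplexes` and `fraction_of_heat`
#' @export
holocomplex_count <- function(kleisin_total, heat_total) {
  stopifnot(kleisin_total >= 0, heat_total >= 0)
  list(holocomplexes = min(kleisin_total, heat_total),
       fraction_of_heat = if (heat_total == 0) NA_real_
                          else kleisin_total / heat_total)
}

#' Condensin I : Condensin II abundance ratio
#'
#' Ratio of the isoform-specific kleisin pools CAP-H (I) / CAP-H2 (II),
#' the limiting indicators of holocomplex number.
#'
#' @param census one-row census (needs `CAP_H`, `CAP_H2` > 0)
#' @return scalar ratio
#' @export
isoform_ratio <- function(census) {
  census <- as.list(census)
  if (as.numeric(census$CAP_H2) <= 0) stop("CAP_H2 total must be positive")
  as.numeric(census$CAP_H) / as.numeric(census$CAP_H2)
}

#' Expected detected localizations per um of chromatid axis
#'
#' The abundance measurement predicts `total / axis_length` complexes
#' per um; a combined labeling-and-detection efficiency below 1 thins
#' this proportionally.
#'
#' @param census one-row census
#' @param subunit which subunit to predict for (default `"CAP_H2"`)
#' @param efficiency combined detection efficiency in (0, 1]
#' @return expected localizations per um of axis
#' @export
predicted_detection <- function(census, subunit = "CAP_H2", efficiency = 1) {
  if (efficiency <= 0 || efficiency > 1)
    stop("efficiency must be in (0, 1]")
  census <- as.list(census)
  efficiency * as.numeric(census[[subunit]]) /
    as.numeric(census$total_axis_length_um)
}
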