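#' Crystallographic model-quality flags for a binding pocket
#'
#' Joins per-residue real-space correlation coefficients (RSCC) and
#' B-factors onto a pocket definition and flags residues whose local fit to
#' the electron density is questionable: `low_rscc` (RSCC below the 0.8
#' cutoff), `damage_prone` (residue types susceptible to radiation damage —
#' Asp, Glu, disulfide-bridged Cys, Met, Tyr — on which conclusions should
#' not rest), and `low_rscc_high_b` (low RSCC coinciding with a B-factor
#' above the pocket median, the stronger indication of a problem region).
#'
#' @param quality_table Data frame with columns `resno`, `resname`, `rscc`,
#'   `bfactor` and optionally `insert` (RSCC computed upstream with
#'   crystallographic software; ligand rows are allowed with `resname` set
#'   to the ligand code).
#' @param pocket A `pocket_definition`; residues in the pocket but missing
#'   from `quality_table` are flagged `missing_data`.
#' @param rscc_cutoff Poor-fit threshold (default 0.8).
#' @param disulfide_cys Residue numbers of cysteines in disulfide bridges
#'   (detection from coordinates uses an S-S distance of 2.5 angstroms; see
#'   [find_disulfides()]).
#' @return A tibble of class `quality_report` with the flags above.
#'   `autoplot()` draws RSCC (green) and B-factor (red) per residue with
#'   the cutoff as a dotted line.
#' @export
quality_report <- function(quality_table, pocket, rscc_cutoff = 0.8,
                           disulfide_cys = integer()) {
  qt <- tibble::as_tibble(quality_table)
  stopifnot(all(c("resno", "resname", "rscc", "bfactor") %in% names(qt)))
  if (!"insert" %in% names(qt)) qt$insert <- ""
  pk <- tibble::as_tibble(pocket)[, c("resno", "insert", "resid")]

  joined <- dplyr::left_join(pk, qt, by = c("resno", "insert"))
  med_b <- stats::median(joined$bfactor, na.rm = TRUE)

  out <- joined |>
    dplyr::transmute(
      resno = .data$resno, insert = .data$insert,
      resname = dplyr::coalesce(.data$resname, .data$resid),
      rscc = .data$rscc, bfactor = .data$bfactor,
      missing_data = is.na(.data$rscc),
      low_rscc = !is.na(.data$rscc) & .data$rscc < rscc_cutoff,
      damage_prone = .data$resname %in% c("ASP", "GLU", "MET", "TYR") |
        (.data$resname == "CYS" & .data$resno %in% disulfide_cys),
      low_rscc_high_b = .data$low_rscc & !is.na(.data$bfactor) &
        .data$bfactor > med_b
    )
  if (any(out$missing_data)) {
    warning(sprintf(
      "%d pocket residue(s) missing from the quality table.",
      sum(out$missing_data)
    ), call. = FALSE)
  }
  structure(out,
            rscc_cutoff = rscc_cutoff, median_bfactor = med_b,
            class = c("quality_report", class(out)))
}

#' Detect disulfide-bridged cysteines from coordinates
#'
#' Flags CYS residues whose SG sulfur lies within `cutoff` of another CYS
#' SG.
#'
#' @param complex A `gpcr_complex`.
#' @param cutoff S-S distance in angstroms (default 2.5).
#' @return Integer vector of residue numbers.
#' @export
find_disulfides <- function(complex, cutoff = 2.5) {
  sg <- dplyr::filter(complex$atoms, .data$resid == "CYS",
                      .data$elety == "SG")
  if (nrow(sg) < 2) return(integer())
  d <- crossdist(as.matrix(sg[, c("x", "y", "z")]),
                 as.matrix(sg[, c("x", "y", "z")]))
  diag(d) <- Inf
  sort(unique(sg$resno[apply(d <= cutoff, 1, any)]))
}

#' @exportS3Method ggplot2::autoplot
autoplot.quality_report <- function(object, ...) {
  cutoff <- attr(object, "rscc_cutoff")
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      residue = factor(
        paste0(.data$resname, .data$resno),
        levels = unique(paste0(.data$resname, .data$resno))
      )
    )
  b_max <- max(df$bfactor, na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(.data$residue, group = 1)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rscc), colour = "#1b7837") +
    ggplot2::geom_point(ggplot2::aes(y = .data$rscc), colour = "#1b7837") +
    ggplot2::geom_line(ggplot2::aes(y = .data$bfactor / b_max),
                       colour = "#b2182b") +
    ggplot2::geom_point(ggplot2::aes(y = .data$bfactor / b_max),
                        colour = "#b2182b", shape = 17) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dotted") +
    ggplot2::scale_y_continuous(
      name = "RSCC (green)",
      sec.axis = ggplot2::sec_axis(~ . * b_max, name = "B-factor (red)")
    ) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
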