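#' Describe a plasmid substrate
#'
#' A plasmid spec carries the physical constants needed to convert between
#' per-molecule event counts, per-Mbp yields and contour lengths in nm.
#'
#' @param name Plasmid name.
#' @param length_bp Plasmid length in base pairs (positive integer).
#' @param bp_nm Contour length per base pair in nm. The B-DNA rise of
#'   0.34 nm/bp is the default.
#' @param circular Is the molecule circular? Only circular substrates are
#'   supported by the topology model.
#'
#' @return An object of class `plasmid_spec`: a list with fields `name`,
#'   `length_bp`, `bp_nm`, `circular` and the derived `contour_nm`.
#' @examples
#' pbr322()
#' plasmid_spec("pUC19", 2686)
#' @export
plasmid_spec <- function(name, length_bp, bp_nm = 0.34, circular = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(length_bp) || length(length_bp) != 1L || length_bp < 1 ||
      length_bp != round(length_bp)) {
    stop("`length_bp` must be a positive whole number", call. = FALSE)
  }
  if (!is.numeric(bp_nm) || length(bp_nm) != 1L || !is.finite(bp_nm) || bp_nm <= 0) {
    stop("`bp_nm` must be a positive finite number", call. = FALSE)
  }
  structure(
    list(
      name = name,
      length_bp = as.integer(length_bp),
      bp_nm = bp_nm,
      circular = isTRUE(circular),
      contour_nm = length_bp * bp_nm
    ),
    class = "plasmid_spec"
  )
}

#' @export
print.plasmid_spec <- function(x, ...) {
  cat(sprintf(
    "<plasmid_spec> %s: %d bp, %.2f nm/bp, contour %.2f nm, %s\n",
    x$name, x$length_bp, x$bp_nm, x$contour_nm,
    if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

#' The pBR322 vector
#'
#' Convenience constructor for the 4361-bp pBR322 plasmid, the classic
#' substrate of relaxation (nicking) assays. Full contour:
#' 4361 bp x 0.34 nm/bp = 1482.74 nm.
#'
#' @return A [plasmid_spec()].
#' @examples
#' pbr322()$contour_nm
#' @export
pbr322 <- function() plasmid_spec("pBR322", 4361L, bp_nm = 0.34, circular = TRUE)

#' Convert per-plasmid event counts to events per Mbp
#'
#' Damage yields are conventionally normalized per megabase pair so plasmids
#' of different sizes are comparable: `events / (length_bp / 1e6)`.
#'
#' @param events_per_plasmid Mean events per plasmid molecule (vectorized,
#'   all values >= 0).
#' @param spec A [plasmid_spec()].
#' @return Events per Mbp, same length as `events_per_plasmid`.
#' @examples
#' per_mbp(0.004361, pbr322()) # 1 event per Mbp
#' @export
per_mbp <- function(events_per_plasmid, spec) {
  stopifnot(inherits(spec, "plasmid_spec"))
  if (any(events_per_plasmid < 0, na.rm = TRUE)) {
    stop("`events_per_plasmid` must be non-negative", call. = FALSE)
  }
  events_per_plasmid / (spec$length_bp / 1e6)
}

#' Convert events per Mbp to per-plasmid event counts
#'
#' Inverse of [per_mbp()].
#'
#' @inheritParams per_mbp
#' @param events_per_mbp Events per Mbp (vectorized).
#' @return Events per plasmid molecule.
#' @export
per_plasmid <- function(events_per_mbp, spec) {
  stopifnot(inherits(spec, "plasmid_spec"))
  events_per_mbp * (spec$length_bp / 1e6)
}

#' Apparent length of a DNA segment
#'
#' @param n_bp Segment length in base pairs.
#' @param bp_nm nm per base pair (default B-DNA 0.34).
#' @return Length in nm.
#' @examples
#' bp_to_nm(42) # 14.28 nm
#' @export
bp_to_nm <- function(n_bp, bp_nm = 0.34) n_bp * bp_nm
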