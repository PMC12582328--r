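#' Sensillum geometry bundle
#'
#' Collects the annotated geometry of one sensillum: the cuticle center-line
#' skeleton (node order base to tip), the soma center of mass, the outer
#' dendrite skeleton with a *declared* orientation, and the cuticle base
#' point. The dendrite orientation is never guessed: it must be declared as
#' `"tip_to_constriction"` or `"constriction_to_tip"` describing the node
#' order of the dendrite skeleton.
#'
#' @param cuticle cuticle center-line [skeleton], base first.
#' @param soma_com numeric length-3 soma center of mass (micrometres).
#' @param dendrite outer-dendrite [skeleton].
#' @param dendrite_orientation `"tip_to_constriction"` or
#'   `"constriction_to_tip"`.
#' @param cuticle_base_point the cuticle base (defaults to the first cuticle
#'   path node).
#' @return an object of class `sensillum_geometry`.
#' @export
sensillum_geometry <- function(cuticle, soma_com, dendrite,
                               dendrite_orientation,
                               cuticle_base_point = NULL) {
  stopifnot(inherits(cuticle, "skeleton"), inherits(dendrite, "skeleton"))
  if (missing(dendrite_orientation) || is.null(dendrite_orientation))
    stop("configuration error: dendrite_orientation must be declared")
  dendrite_orientation <- match.arg(dendrite_orientation,
                                    c("tip_to_constriction",
                                      "constriction_to_tip"))
  if (path_length(cuticle) <= 0) stop("geometry error: degenerate cuticle")
  if (path_length(dendrite) <= 0) stop("geometry error: degenerate dendrite")
  if (is.null(cuticle_base_point))
    cuticle_base_point <- cuticle$path_xyz[1, ]
  structure(list(cuticle = cuticle, soma_com = as.numeric(soma_com),
                 dendrite = dendrite,
                 dendrite_orientation = dendrite_orientation,
                 cuticle_base_point = as.numeric(cuticle_base_point)),
            class = "sensillum_geometry")
}

#' Cuticle proportion of the soma center of mass
#'
#' Normalised position of the soma COM along the cuticle center-line: 0 at
#' the cuticle base, 1 at the tip. When the nearest location is the base
#' endpoint itself, the bottom cuticle segment is extrapolated backward and
#' the COM re-projected, giving a negative proportion (C = -1 means one full
#' cuticle length below the base, measured as arc length along the
#' extrapolated ray). A COM whose nearest location lies strictly inside the
#' path is reported from the un-extrapolated projection even when it sits
#' laterally.
#'
#' @param geom a [sensillum_geometry].
#' @return the cuticle proportion C (a real number, at most 1).
#' @export
cuticle_proportion <- function(geom) {
  stopifnot(inherits(geom, "sensillum_geometry"))
  pr <- project_point(geom$cuticle, geom$soma_com)
  if (pr$s_um <= 0) {
    pr <- project_point(geom$cuticle, geom$soma_com, extend_base = TRUE)
  }
  pr$t_norm
}

#' Soma depth below the cuticle base
#'
#' Depth is `D = -C x L` where C is the cuticle proportion and L the cuticle
#' length. Positive D places the soma COM below the cuticle base, D = 0 at
#' the base, negative D above the base (which typically indicates a
#' laterally placed soma).
#'
#' @param C cuticle proportion (from [cuticle_proportion()]).
#' @param L cuticle length in micrometres (> 0).
#' @return list with `C`, `D_um` and `classification` (one of
#'   `"below_base"`, `"at_base"`, `"above_base"`).
#' @export
soma_depth <- function(C, L) {
  if (!is.numeric(L) || L <= 0) stop("domain error: L must be positive")
  D <- -C * L
  cls <- if (D > 0) "below_base" else if (D == 0) "at_base" else "above_base"
  list(C = C, D_um = D, classification = cls)
}

#' Proportion of the outer dendrite encapsulated by the cuticle
#'
#' Projects the cuticle base point onto the outer-dendrite skeleton and
#' reports the normalised position of the projection with 0 at the dendrite
#' tip and 1 at the ciliary constriction: the fraction of outer-dendrite
#' length lying above the cuticle base (hence with direct odorant/CO2
#' access).
#'
#' @param geom a [sensillum_geometry] with declared dendrite orientation.
#' @return proportion in `[0, 1]`.
#' @export
encapsulated_proportion <- function(geom) {
  stopifnot(inherits(geom, "sensillum_geometry"))
  t <- project_point(geom$dendrite, geom$cuticle_base_point)$t_norm
  if (geom$dendrite_orientation == "tip_to_constriction") t else 1 - t
}

#' Full position metrics for one sensillum
#'
#' Convenience wrapper returning one result row: cuticle proportion, depth,
#' classification and encapsulated proportion.
#'
#' @param geom a [sensillum_geometry].
#' @return one-row data frame with `C`, `D_um`, `classification`,
#'   `encapsulated_proportion`.
#' @export
position_metrics <- function(geom) {
  C <- cuticle_proportion(geom)
  d <- soma_depth(C, path_length(geom$cuticle))
  data.frame(C = C, D_um = d$D_um, classification = d$classification,
             encapsulated_proportion = encapsulated_proportion(geom))
}

#' Read a sensillum geometry bundle from JSON
#'
#' The bundle references SWC files (relative to the JSON's directory unless
#' absolute), explicit points, and the dendrite orientation flag:
#' `{"cuticle_swc": ..., "dendrite_swc": ..., "dendrite_orientation": ...,
#' "soma_com": [x,y,z], "cuticle_base_point": [x,y,z] (optional)}`.
#'
#' @param path JSON file path.
#' @return a [sensillum_geometry].
#' @export
read_sensillum_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  sensillum_geometry(
    cuticle = read_swc(resolve(cfg$cuticle_swc)),
    soma_com = as.numeric(cfg$soma_com),
    dendrite = read_swc(resolve(cfg$dendrite_swc)),
    dendrite_orientation = cfg$dendrite_orientation,
    cuticle_base_point = if (!is.null(cfg$cuticle_base_point))
      as.numeric(cfg$cuticle_base_point) else NULL)
}
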