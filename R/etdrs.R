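# ETDRS macular grid and retinal layer vocabulary.

#' ETDRS sector codes
#'
#' The nine macular sectors of the ETDRS grid: the central subfield (`C`),
#' four inner-ring sectors at 1--3 mm from the fovea (`IS`, `II`, `IN`, `IT`)
#' and four outer-ring sectors at 3--6 mm (`OS`, `OI`, `ON`, `OT`).
#'
#' @return Character vector of the 9 sector codes.
#' @export
etdrs_sectors <- function() {
  c("C", "IS", "II", "IN", "IT", "OS", "OI", "ON", "OT")
}

#' Ring of each ETDRS sector
#'
#' @param sector character vector of sector codes.
#' @return Character vector, one of `"central"`, `"inner"`, `"outer"`.
#' @export
sector_ring <- function(sector) {
  rings <- c(C = "central",
             IS = "inner", II = "inner", IN = "inner", IT = "inner",
             OS = "outer", OI = "outer", ON = "outer", OT = "outer")
  bad <- setdiff(sector, names(rings))
  if (length(bad) > 0L) {
    stop("unknown ETDRS sector code(s): ", paste(bad, collapse = ", "))
  }
  unname(rings[sector])
}

#' Sectors belonging to a ring
#'
#' @param ring `"central"`, `"inner"` or `"outer"`.
#' @return Character vector of sector codes in that ring.
#' @export
ring_sectors <- function(ring) {
  ring <- match.arg(ring, c("central", "inner", "outer"))
  switch(ring,
         central = "C",
         inner   = c("IS", "II", "IN", "IT"),
         outer   = c("OS", "OI", "ON", "OT"))
}

#' Primary retinal layers
#'
#' The seven segmented layers used as network nodes: retinal nerve fiber
#' layer (RNFL), ganglion cell layer (GCL), inner plexiform layer (IPL),
#' inner nuclear layer (INL), outer plexiform layer (OPL), outer nuclear
#' layer (ONL) and retinal pigment epithelium (RPE).
#'
#' @return Character vector of the 7 layer codes.
#' @export
primary_layers <- function() {
  c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL", "RPE")
}

#' Composite layers
#'
#' Derived composites: inner retina (IR), outer retina (OR) and total retinal
#' thickness (TRT). Their layer membership is configurable; see
#' [default_composite_scheme()]. Composites are never network nodes.
#'
#' @return Character vector `c("IR", "OR", "TRT")`.
#' @export
composite_layers <- function() {
  c("IR", "OR", "TRT")
}

#' Default composite-layer scheme
#'
#' Maps each composite layer to the primary layers it sums over. The default
#' takes IR = RNFL + GCL + IPL + INL, OR = OPL + ONL + RPE and TRT = all
#' seven. Device exports differ in where they cut the inner/outer boundary,
#' so the scheme is an explicit, named configuration rather than a constant.
#'
#' @return Named list of character vectors of primary-layer codes.
#' @export
default_composite_scheme <- function() {
  list(IR  = c("RNFL", "GCL", "IPL", "INL"),
       OR  = c("OPL", "ONL", "RPE"),
       TRT = primary_layers())
}

#' Network node table
#'
#' The 63 nodes of the structural covariance network: every (primary layer,
#' sector) pair in layer-major order. Node labels follow the
#' `LAYER_SECTOR` column convention (e.g. `RNFL_IS`).
#'
#' @return A data.frame with columns `layer`, `sector`, `label` (63 rows).
#' @export
scn_nodes <- function() {
  grid <- expand.grid(sector = etdrs_sectors(), layer = primary_layers(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(layer = grid$layer, sector = grid$sector,
             label = paste(grid$layer, grid$sector, sep = "_"),
             stringsAsFactors = FALSE)
}

# Internal: the 63 LAYER_SECTOR column names in canonical order.
node_labels <- function() scn_nodes()$label

cohort_groups <- function() c("HC", "DWOR")
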