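#' Gray-white matter tissue contrast (GWC)
#'
#' Percentage contrast between white- and gray-matter T1 intensities at
#' each vertex:
#' \deqn{GWC_i = 100 (WMI_i - GMI_i) / (0.5 (WMI_i + GMI_i))}
#' with WMI sampled at -1 mm below the boundary and GMI at a 30% CT
#' projection fraction. A decreased GWC corresponds to a lower contrast
#' between the two tissue intensities, i.e. a "blurring" of the gray-white
#' transition zone. Vertices where either input is invalid or where
#' `WMI + GMI <= 0` are masked.
#'
#' @param wmi [vertex_map()] of white-matter T1 intensity (-1 mm).
#' @param gmi [vertex_map()] of gray-matter T1 intensity (30% CT).
#' @return a [vertex_map()] with modality `"GWC"`.
#' @export
compute_gwc <- function(wmi, gmi) {
  if (length(wmi$values) != length(gmi$values))
    stop_fmt("geometry_error",
             "WMI (%d) and GMI (%d) maps are on different meshes",
             length(wmi$values), length(gmi$values))
  denom <- 0.5 * (wmi$values + gmi$values)
  valid <- wmi$valid & gmi$valid & !is.na(denom) & denom > 0
  gwc <- ifelse(valid, 100 * (wmi$values - gmi$values) / denom, NA_real_)
  vertex_map(gwc, valid, mesh_id = wmi$mesh_id, modality = "GWC")
}
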