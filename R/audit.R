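# Model complexity audit: walks the architecture graph and applies the
# counting rules
#   Params = sum Kh*Kw*Cin*Cout          (+Cout where a bias exists)
#   FLOPs  = sum Kh*Kw*Cin*Cout*H*W      (multiply-accumulate pairs over the
#                                         output map; no factor 2)
#   GFLOPs = FLOPs / 1e9
# Normalization parameters/ops and attention matrix-product MACs are
# itemized as their own rows, so the totals are reproducible line by line.

#' Audit trainable parameters and FLOPs of a detector
#'
#' @param model a [StageNet-class] (or any network built by the package).
#' @param inputSize square input side in pixels (must be divisible by 32).
#' @return An [AuditReport-class]; its layer table has one row per
#'   convolution, normalization, fusion-weight and attention entry.
#' @examples
#' rep <- auditModel(stageNet(stageNetConfig("tiny")), 320)
#' totalParams(rep)
#' @export
auditModel <- function(model, inputSize = 640) {
  m <- model_env(model)
  if (inputSize %% 32 != 0) stop("inputSize must be divisible by 32")
  rows <- lapply(m$graph, function(r) {
    side <- inputSize / r$down
    data.frame(name = r$name, kind = r$kind, kh = r$kh, kw = r$kw,
               cin = r$cin, cout = r$cout, stride = r$stride,
               hout = side, wout = side, params = r$params,
               flops = r$macs_per_px * side * side)
  })
  layers <- do.call(rbind, rows)
  tot_p <- sum(layers$params)
  tot_f <- sum(layers$flops)
  # cross-check: the graph walk must account for every stored parameter
  stopifnot(tot_p == net_nparams(m))
  new("AuditReport", layers = layers, totalParams = tot_p, totalFlops = tot_f,
      gflops = tot_f / 1e9)
}

#' Write an audit report as per-layer CSV plus JSON totals
#'
#' @param report an [AuditReport-class].
#' @param csvPath per-layer CSV output path.
#' @param jsonPath totals JSON output path (NULL to skip).
#' @return `csvPath`, invisibly.
#' @export
writeAuditReport <- function(report, csvPath, jsonPath = NULL) {
  write.csv(layerTable(report), csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(total_params = report@totalParams,
           total_params_m = report@totalParams / 1e6,
           total_flops = report@totalFlops,
           gflops = report@gflops),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(csvPath)
}

#' Count convolution layers under two conventions
#'
#' The "Conv Layers" figure of backbone summaries is ambiguous about whether
#' the pointwise/depthwise parts of a separable block count individually;
#' both countings are reported.
#'
#' @param model a [StageNet-class].
#' @return named list: `all` (every conv, depthwise and pointwise separately)
#'   and `merged` (each depthwise-separable expand/dw/project triple counted
#'   once).
#' @export
convLayerCounts <- function(model) {
  m <- model_env(model)
  kinds <- vapply(m$graph, function(r) r$kind, character(1))
  names <- vapply(m$graph, function(r) r$name, character(1))
  convs <- names[kinds %in% c("conv", "dwconv")]
  uib <- unique(sub("\\.(exp|dw|proj)$", "", grep("\\.(exp|dw|proj)$", convs, value = TRUE)))
  other <- grep("\\.(exp|dw|proj)$", convs, invert = TRUE, value = TRUE)
  list(all = length(convs), merged = length(uib) + length(other))
}
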