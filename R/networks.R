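#' Network definitions
#'
#' A network map assigns each region-of-interest (ROI) label to exactly one
#' named functional network (e.g. DMN, DAN, SAN, VIS). The name `"brain"` is
#' reserved: it always denotes the union of all ROIs and must not be declared
#' explicitly.
#'
#' @param ... Named character vectors, one per network, each listing the ROI
#'   labels belonging to that network.
#'
#' @return A named list of character vectors with class `"network_map"`.
#' @examples
#' nm <- network_map(DMN = c("PCC", "mPFC"), VIS = c("V1", "V2"))
#' network_names(nm)
#' @export
network_map <- function(...) {
  nets <- list(...)
  if (length(nets) == 1 && is.list(nets[[1]]) && is.null(names(nets)[1])) {
    nets <- nets[[1]]
  }
  validate_network_map(nets)
}

#' @rdname network_map
#' @param nets A named list of character vectors (network name -> ROI labels).
#' @export
validate_network_map <- function(nets) {
  if (length(nets) == 0 || is.null(names(nets)) || any(names(nets) == "")) {
    abort("A network map needs at least one named network.")
  }
  if ("brain" %in% names(nets)) {
    abort("\"brain\" is reserved for the union of all ROIs; do not declare it.")
  }
  nets <- lapply(nets, as.character)
  if (any(lengths(nets) == 0)) {
    abort("Networks must be non-empty.")
  }
  rois <- unlist(nets, use.names = FALSE)
  dup <- unique(rois[duplicated(rois)])
  if (length(dup) > 0) {
    abort(paste0(
      "Each ROI may belong to exactly one named network; duplicated: ",
      paste(dup, collapse = ", ")
    ))
  }
  structure(nets, class = c("network_map", "list"))
}

#' @rdname network_map
#' @param map A `network_map`.
#' @export
network_names <- function(map) names(map)

#' ROI labels of one network
#'
#' @param map A [network_map()].
#' @param network Network name; `"brain"` returns all ROIs in map order.
#' @return Character vector of ROI labels.
#' @export
network_rois <- function(map, network) {
  if (identical(network, "brain")) {
    return(unlist(map, use.names = FALSE))
  }
  if (!network %in% names(map)) {
    abort(paste0("Unknown network: ", network))
  }
  map[[network]]
}

#' All ROI labels covered by a network map
#'
#' @param map A [network_map()].
#' @return Character vector of ROI labels in map order.
#' @export
roi_labels <- function(map) unlist(map, use.names = FALSE)

#' Partition ROI labels into named networks
#'
#' Splits a vector of ROI labels into contiguous, approximately equal-sized
#' named networks. Convenient for building synthetic cohorts at arbitrary ROI
#' counts.
#'
#' @param rois Character vector of ROI labels, or a single integer n to use
#'   labels `ROI01..ROIn`.
#' @param networks Character vector of network names (default DMN, DAN, SAN,
#'   VIS). Must not exceed the number of ROIs.
#' @return A [network_map()].
#' @examples
#' split_network_map(8, c("DMN", "VIS"))
#' @export
split_network_map <- function(rois, networks = c("DMN", "DAN", "SAN", "VIS")) {
  if (is.numeric(rois) && length(rois) == 1) {
    rois <- sprintf("ROI%02d", seq_len(rois))
  }
  rois <- as.character(rois)
  if (length(networks) > length(rois)) {
    abort("More networks than ROIs.")
  }
  idx <- sort(rep_len(seq_along(networks), length(rois)))
  validate_network_map(split(rois, factor(networks[idx], levels = networks)))
}

#' Default cortical ROI-to-network mapping
#'
#' Loads the Desikan-Killiany-style 68-ROI mapping shipped with the package
#' (`inst/extdata/dk_networks.json`). The assignment of atlas parcels to the
#' default mode (DMN), dorsal attention (DAN), salience (SAN) and visual (VIS)
#' networks is a stylized, editable default intended for synthetic cohorts and
#' examples; analyses of real data should supply a mapping appropriate to the
#' parcellation actually used.
#'
#' @param path Optional path to an alternative JSON mapping
#'   (`{"network": ["roi", ...], ...}`).
#' @return A [network_map()].
#' @export
dk_network_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dk_networks.json", package = "dynfc")
  nets <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_network_map(nets)
}

#' @export
print.network_map <- function(x, ...) {
  cat("<network_map> ", length(x), " networks, ",
    length(roi_labels(x)), " ROIs\n",
    sep = ""
  )
  for (nm in names(x)) {
    cat("  ", format(nm, width = 6), " (", length(x[[nm]]), "): ",
      paste(utils::head(x[[nm]], 4), collapse = ", "),
      if (length(x[[nm]]) > 4) ", ..." else "", "\n",
      sep = ""
    )
  }
  invisible(x)
}
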