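#' Default 32-channel 10-20 montage
#'
#' A schematic 2-D head projection (nose up, unit head radius) of a
#' 32-electrode cap laid out on the international 10-20 system. The set
#' contains every electrode used by the ERP region of interest (Pz, P5, P6,
#' P7, P8, PO3, PO4, O1, O2) plus the standard frontal/central/temporal
#' complement. Coordinates are schematic: they are used only to derive a
#' neighbourhood graph for cluster-based inference and for plotting, not for
#' source modelling.
#'
#' @return A data.frame with columns `label`, `x`, `y`.
#' @export
#' @examples
#' m <- default_montage()
#' nrow(m)  # 32
default_montage <- function() {
  tab <- c(
    "Fp1", -0.25,  0.90,   "Fpz",  0.00,  0.95,   "Fp2",  0.25,  0.90,
    "F7",  -0.72,  0.58,   "F3",  -0.35,  0.62,   "Fz",   0.00,  0.65,
    "F4",   0.35,  0.62,   "F8",   0.72,  0.58,
    "FC5", -0.60,  0.30,   "FC1", -0.22,  0.32,   "FC2",  0.22,  0.32,
    "FC6",  0.60,  0.30,
    "T7",  -0.82,  0.00,   "C3",  -0.42,  0.00,   "Cz",   0.00,  0.00,
    "C4",   0.42,  0.00,   "T8",   0.82,  0.00,
    "CP5", -0.60, -0.30,   "CP1", -0.22, -0.32,   "CP2",  0.22, -0.32,
    "CP6",  0.60, -0.30,
    "P7",  -0.80, -0.55,   "P5",  -0.58, -0.60,   "P3",  -0.36, -0.63,
    "Pz",   0.00, -0.65,   "P4",   0.36, -0.63,   "P6",   0.58, -0.60,
    "P8",   0.80, -0.55,
    "PO3", -0.28, -0.82,   "PO4",  0.28, -0.82,
    "O1",  -0.22, -0.95,   "O2",   0.22, -0.95
  )
  m <- matrix(tab, ncol = 3, byrow = TRUE)
  data.frame(label = m[, 1],
             x = as.numeric(m[, 2]),
             y = as.numeric(m[, 3]),
             stringsAsFactors = FALSE)
}

#' Parieto-occipital region of interest for ERP quantification
#'
#' Electrode labels over parietal and occipital cortex conventionally used to
#' quantify target-evoked N1 and P3 components in visuo-spatial attention
#' tasks.
#'
#' @return Character vector of channel labels.
#' @export
erp_roi <- function() {
  c("Pz", "P5", "P6", "P7", "P8", "PO3", "PO4", "O1", "O2")
}

#' Electrode adjacency from a 2-D montage
#'
#' Two electrodes are neighbours when their planar distance is below
#' `factor` times the median nearest-neighbour distance of the montage.
#' This yields a sparse, spatially local graph suitable for cluster-based
#' permutation inference; users with a measured cap geometry can substitute
#' their own edge list.
#'
#' @param montage data.frame with `label`, `x`, `y` (see [default_montage()]).
#' @param factor multiplier on the median nearest-neighbour distance
#'   (default 1.3).
#' @return Symmetric logical adjacency matrix with dimnames = labels.
#' @export
montage_adjacency <- function(montage = default_montage(), factor = 1.3) {
  stopifnot(all(c("label", "x", "y") %in% names(montage)), factor > 0)
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  diag(d) <- Inf
  thr <- factor * stats::median(apply(d, 1, min))
  adj <- d < thr
  diag(adj) <- FALSE
  dimnames(adj) <- list(montage$label, montage$label)
  adj
}

#' Write a montage and its adjacency as TSV files
#'
#' @param montage data.frame with `label`, `x`, `y`.
#' @param montage_path,adjacency_path output file paths (`NULL` skips).
#' @param factor passed to [montage_adjacency()].
#' @return Invisibly, the adjacency matrix.
#' @export
write_montage <- function(montage = default_montage(), montage_path = NULL,
                          adjacency_path = NULL, factor = 1.3) {
  adj <- montage_adjacency(montage, factor)
  if (!is.null(montage_path))
    utils::write.table(montage, montage_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(adjacency_path)) {
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    edges <- data.frame(from = rownames(adj)[idx[, 1]],
                        to = colnames(adj)[idx[, 2]])
    utils::write.table(edges, adjacency_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(adj)
}

#' Read an electrode adjacency edge list (TSV) into a matrix
#'
#' @param path TSV file with columns `from`, `to`.
#' @param labels full channel label set (edges must be a subset).
#' @return Symmetric logical adjacency matrix.
#' @export
read_adjacency <- function(path, labels) {
  edges <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  bad <- setdiff(unique(c(edges$from, edges$to)), labels)
  if (length(bad) > 0)
    stop("adjacency refers to unknown electrodes: ", paste(bad, collapse = ", "))
  adj <- matrix(FALSE, length(labels), length(labels),
                dimnames = list(labels, labels))
  for (i in seq_len(nrow(edges))) {
    adj[edges$from[i], edges$to[i]] <- TRUE
    adj[edges$to[i], edges$from[i]] <- TRUE
  }
  adj
}
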