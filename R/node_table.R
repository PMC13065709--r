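#' Build a node table defining the a-priori community partition
#'
#' The node table is the single source of truth for node identity and order:
#' connectivity matrix files carry no labels, and row/column \code{i} of every
#' matrix is node \code{node_id = i - 1}. Each node belongs to exactly one
#' intrinsic connectivity network (ICN); the network labels define the
#' community partition used by the participation coefficient.
#'
#' @param cortical_spec data.frame with columns \code{hemisphere}
#'   (\code{"left"}/\code{"right"}), \code{network}, \code{parcel_name}.
#' @param subcortical_spec data.frame with columns \code{hemisphere} and
#'   \code{structure_name}, or \code{NULL} for a cortex-only table. All
#'   subcortical structures are assigned to one extra network,
#'   \code{subcortical_network}.
#' @param subcortical_network label for the subcortical community.
#' @return data.frame of class \code{"node_table"} with columns
#'   \code{node_id} (0-based, contiguous), \code{hemisphere}, \code{network},
#'   \code{parcel_name}.
#' @seealso [default_node_table()] for the packaged 412-node / 8-network table.
#' @export
build_node_table <- function(cortical_spec, subcortical_spec = NULL,
                             subcortical_network = "Subcortical") {
  if (is.null(cortical_spec) || nrow(cortical_spec) == 0L)
    stop("cortical_spec must contain at least one parcel", call. = FALSE)
  stopifnot(all(c("hemisphere", "network", "parcel_name") %in% names(cortical_spec)))
  cort <- data.frame(
    hemisphere  = as.character(cortical_spec$hemisphere),
    network     = as.character(cortical_spec$network),
    parcel_name = as.character(cortical_spec$parcel_name),
    stringsAsFactors = FALSE
  )
  if (!is.null(subcortical_spec) && nrow(subcortical_spec) > 0L) {
    stopifnot(all(c("hemisphere", "structure_name") %in% names(subcortical_spec)))
    if (subcortical_network %in% cort$network)
      stop("subcortical network label collides with a cortical network",
           call. = FALSE)
    sub <- data.frame(
      hemisphere  = as.character(subcortical_spec$hemisphere),
      network     = subcortical_network,
      parcel_name = as.character(subcortical_spec$structure_name),
      stringsAsFactors = FALSE
    )
    tab <- rbind(cort, sub)
  } else {
    tab <- cort
  }
  bad_hemi <- setdiff(unique(tab$hemisphere), c("left", "right"))
  if (length(bad_hemi))
    stop("unknown hemisphere label(s): ", paste(bad_hemi, collapse = ", "),
         call. = FALSE)
  key <- paste(tab$hemisphere, tab$parcel_name)
  if (anyDuplicated(key))
    stop("duplicate (hemisphere, parcel_name) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  tab$node_id <- seq_len(nrow(tab)) - 1L
  tab <- tab[, c("node_id", "hemisphere", "network", "parcel_name")]
  class(tab) <- c("node_table", "data.frame")
  tab
}

# Parcel counts per network per hemisphere for the default cortical sheet:
# 200 parcels per hemisphere over 7 ICNs (total 400).
.default_cortical_counts <- function() {
  c(Visual = 30L, Somatomotor = 40L, DorsalAttention = 23L,
    VentralAttention = 22L, Limbic = 13L, Control = 30L, Default = 42L)
}

.default_parcel_prefix <- c(
  Visual = "Vis", Somatomotor = "SomMot", DorsalAttention = "DorsAttn",
  VentralAttention = "SalVentAttn", Limbic = "Limbic", Control = "Cont",
  Default = "Default"
)

#' Default 412-node, 8-network node table
#'
#' 400 cortical parcels over 7 canonical ICNs (200 per hemisphere) plus 12
#' subcortical structures (6 per hemisphere: thalamus, caudate, putamen,
#' pallidum, hippocampus, amygdala) grouped as their own eighth network.
#'
#' A CSV copy of this table ships with the package at
#' \code{system.file("extdata", "node_table_412.csv", package = "netcontrast")}.
#'
#' @param subcortical logical; include the 12 subcortical nodes (default TRUE).
#' @return a \code{node_table} with 412 rows (400 if \code{subcortical = FALSE}).
#' @export
default_node_table <- function(subcortical = TRUE) {
  counts <- .default_cortical_counts()
  cort <- do.call(rbind, lapply(c("left", "right"), function(h) {
    do.call(rbind, lapply(names(counts), function(net) {
      data.frame(
        hemisphere  = h,
        network     = net,
        parcel_name = paste0(.default_parcel_prefix[[net]], "_", seq_len(counts[[net]])),
        stringsAsFactors = FALSE
      )
    }))
  }))
  sub <- NULL
  if (subcortical) {
    structures <- c("Thalamus", "Caudate", "Putamen", "Pallidum",
                    "Hippocampus", "Amygdala")
    sub <- data.frame(
      hemisphere     = rep(c("left", "right"), each = length(structures)),
      structure_name = rep(structures, times = 2L),
      stringsAsFactors = FALSE
    )
  }
  build_node_table(cort, sub)
}

#' Number of nodes in a node table
#' @param node_table a \code{node_table}.
#' @return integer node count.
#' @export
n_nodes <- function(node_table) nrow(node_table)

#' Community membership vector from a node table
#'
#' @param node_table a \code{node_table}.
#' @return integer vector of community ids (1..M) in node order, with the
#'   network labels as a \code{"labels"} attribute.
#' @export
node_communities <- function(node_table) {
  nets <- unique(node_table$network)
  m <- match(node_table$network, nets)
  attr(m, "labels") <- nets
  m
}

#' Read / write a node table as CSV
#'
#' Columns: \code{node_id, hemisphere, network, parcel_name}. \code{node_id}
#' must be 0-based and contiguous in file order.
#'
#' @param path CSV file path.
#' @return \code{read_node_table}: a \code{node_table};
#'   \code{write_node_table}: \code{path}, invisibly.
#' @export
read_node_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("node_id", "hemisphere", "network", "parcel_name") %in% names(tab)))
  if (!identical(as.integer(tab$node_id), seq_len(nrow(tab)) - 1L))
    stop("node_id must be contiguous 0..N-1 in file order", call. = FALSE)
  tab$node_id <- as.integer(tab$node_id)
  class(tab) <- c("node_table", "data.frame")
  tab
}

#' @rdname read_node_table
#' @param node_table a \code{node_table} to write.
#' @export
write_node_table <- function(node_table, path) {
  utils::write.csv(as.data.frame(node_table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
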