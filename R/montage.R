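#' Electrode montage adjacency
#'
#' Builds the neighbor graph used to form electrode clusters. By default a
#' synthetic equidistant cap layout is generated (a sunflower arrangement on
#' a disk, mimicking an equidistant 60-channel montage projected to 2-D) and
#' electrodes are declared neighbors when their distance is at most
#' `threshold_mult` times the median nearest-neighbor distance. The graph is
#' symmetric and irreflexive, and the default layout is connected.
#'
#' @param n_electrodes Number of electrodes (default 60); ignored when
#'   `positions` is supplied.
#' @param positions Optional matrix/data frame of 2-D positions (rows =
#'   electrodes) with optional rownames as electrode names.
#' @param names Optional electrode names.
#' @param threshold_mult Distance threshold as a multiple of the median
#'   nearest-neighbor distance (default 1.5).
#' @param edges Optional explicit two-column edge matrix/data frame of
#'   electrode names; overrides the distance rule.
#' @return An object of class `montage`: list with `names`, `positions`
#'   (tibble `electrode`, `x`, `y`), and `edges` (tibble `from`, `to`).
#' @export
#' @examples
#' m <- montage_adjacency(60)
#' nrow(m$edges)
montage_adjacency <- function(n_electrodes = 60, positions = NULL, names = NULL,
                              threshold_mult = 1.5, edges = NULL) {
  if (is.null(positions)) {
    positions <- sunflower_layout(n_electrodes)
  } else {
    positions <- as.matrix(positions)
    n_electrodes <- nrow(positions)
  }
  names <- names %||% rownames(positions) %||% sprintf("E%02d", seq_len(n_electrodes))
  rownames(positions) <- names

  if (is.null(edges)) {
    d <- as.matrix(dist(positions))
    diag(d) <- Inf
    nn <- apply(d, 1, min)
    thresh <- threshold_mult * median(nn)
    idx <- which(d <= thresh & upper.tri(d), arr.ind = TRUE)
    edges <- tibble(from = names[idx[, 1]], to = names[idx[, 2]])
  } else {
    edges <- as_tibble(as.data.frame(edges))
    colnames(edges)[1:2] <- c("from", "to")
    if (!all(c(edges$from, edges$to) %in% names)) {
      abort("edge list refers to unknown electrodes.", class = "aperiodic_config_error")
    }
    edges <- dplyr::filter(edges, .data$from != .data$to)
  }

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = names))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warn(sprintf("montage adjacency is disconnected (%d components): %s",
                 comp$no,
                 paste(tapply(names, comp$membership, paste, collapse = ","),
                       collapse = " | ")))
  }
  structure(
    list(
      names = names,
      positions = tibble(electrode = names,
                         x = positions[, 1], y = positions[, 2]),
      edges = edges
    ),
    class = "montage"
  )
}

# Sunflower (Fermat spiral) layout: n approximately equidistant points on a
# unit disk.
sunflower_layout <- function(n) {
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / n)
  cbind(x = r * cos(i * golden), y = r * sin(i * golden))
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes, %d adjacency edges\n",
              length(x$names), nrow(x$edges)))
  invisible(x)
}

# Internal: adjacency as an index list (per electrode, integer neighbors).
adjacency_index <- function(montage) {
  nm <- montage$names
  adj <- vector("list", length(nm))
  fi <- match(montage$edges$from, nm)
  ti <- match(montage$edges$to, nm)
  for (k in seq_along(fi)) {
    adj[[fi[k]]] <- c(adj[[fi[k]]], ti[k])
    adj[[ti[k]]] <- c(adj[[ti[k]]], fi[k])
  }
  adj
}

# Internal: connected components among `active` (integer indices), given the
# adjacency list. Returns a list of integer vectors.
connected_groups <- function(active, adj) {
  if (length(active) == 0) return(list())
  remaining <- active
  groups <- list()
  in_active <- logical(length(adj)); in_active[active] <- TRUE
  while (length(remaining)) {
    queue <- remaining[1]
    seen <- queue
    remaining <- remaining[-1]
    while (length(queue)) {
      nb <- unique(unlist(adj[queue]))
      nb <- nb[in_active[nb] & !(nb %in% seen)]
      seen <- c(seen, nb)
      remaining <- setdiff(remaining, nb)
      queue <- nb
    }
    groups[[length(groups) + 1]] <- sort(seen)
  }
  groups
}
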