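#' Build a contiguity adjacency matrix from an edge list
#'
#' Constructs the binary symmetric adjacency matrix W used by the CAR model:
#' W\[i,j\] = 1 when the two areas share a border, 0 otherwise, with zero
#' diagonal. Duplicate edges (including reversed duplicates) are collapsed
#' with a warning.
#'
#' @param area_ids area identifiers in the order of the model's
#'   observations.
#' @param edges two-column data frame or matrix of unordered border pairs.
#' @return square 0/1 matrix with `area_ids` as dimnames.
#' @export
adjacency_from_edges <- function(area_ids, edges) {
  if (anyDuplicated(area_ids))
    stop("area_ids must be unique", call. = FALSE)
  n <- length(area_ids)
  W <- matrix(0, n, n, dimnames = list(area_ids, area_ids))
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0L) {
    a <- match(as.character(edges[[1L]]), area_ids)
    b <- match(as.character(edges[[2L]]), area_ids)
    if (anyNA(a) || anyNA(b)) {
      bad <- unique(c(as.character(edges[[1L]])[is.na(a)],
                      as.character(edges[[2L]])[is.na(b)]))
      stop("edge references unknown area(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(a == b))
      stop("self-loop edge(s) not allowed: ",
           paste(unique(as.character(edges[[1L]])[a == b]), collapse = ", "),
           call. = FALSE)
    key <- paste(pmin(a, b), pmax(a, b))
    if (anyDuplicated(key)) {
      warning("duplicate edge(s) collapsed", call. = FALSE)
      keep <- !duplicated(key)
      a <- a[keep]; b <- b[keep]
    }
    W[cbind(a, b)] <- 1
    W[cbind(b, a)] <- 1
  }
  W
}

validate_adjacency <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("W must be a square matrix", call. = FALSE)
  if (!all(W %in% c(0, 1)))
    stop("W entries must be 0 or 1", call. = FALSE)
  if (any(diag(W) != 0))
    stop("W must have a zero diagonal", call. = FALSE)
  if (!isTRUE(all.equal(W, t(W))))
    stop("W must be symmetric", call. = FALSE)
  invisible(W)
}

#' Connected components and islands of an adjacency structure
#'
#' Labels connected components of the contiguity graph by breadth-first
#' search and enumerates islands (areas without neighbours). Islands keep a
#' valid spatial prior under the Leroux form for rho < 1 — their random
#' effect reverts to an exchangeable prior — but are worth knowing about.
#'
#' @param W adjacency matrix from [adjacency_from_edges()].
#' @return list with `component` (integer label per area), `n_components`,
#'   and `islands` (ids of degree-0 areas). Islands trigger a warning.
#' @export
check_connectivity <- function(W) {
  validate_adjacency(W)
  n <- nrow(W)
  comp <- integer(n)
  label <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    label <- label + 1L
    queue <- s
    comp[s] <- label
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(W[v, ] == 1 & comp == 0L)
      comp[nb] <- label
      queue <- c(queue, nb)
    }
  }
  islands <- rownames(W)[rowSums(W) == 0]
  if (is.null(islands)) islands <- which(rowSums(W) == 0)
  if (length(islands) > 0L)
    warning("island area(s) with no neighbours: ",
            paste(islands, collapse = ", "), call. = FALSE)
  list(component = setNames(comp, rownames(W)),
       n_components = label, islands = islands)
}

#' Read an area edge list from a delimited file
#'
#' @param path file with two id columns (`area_a`, `area_b`), tab- or
#'   whitespace-delimited, optional header.
#' @param header whether the first line is a header.
#' @return two-column data frame `area_a`, `area_b`.
#' @export
read_edge_list <- function(path, header = TRUE) {
  e <- read.delim(path, header = header, sep = "",
                  colClasses = "character")
  if (ncol(e) < 2L) stop("edge list needs two columns", call. = FALSE)
  e <- e[, 1:2]
  names(e) <- c("area_a", "area_b")
  e
}
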