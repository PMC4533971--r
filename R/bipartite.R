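#' Construct a bipartite regime shift-driver network
#'
#' The central data structure of the package: a binary incidence matrix whose
#' rows are regime shifts and whose columns are drivers. A cell is 1 when the
#' academic literature links the driver causally to the regime shift.
#'
#' @param incidence numeric/integer matrix of 0/1 indicators with rownames
#'   (regime shifts) and colnames (drivers). Row and column names must be
#'   unique within their side.
#' @param provenance optional data frame of per-link citation strings with
#'   columns `shift`, `driver`, `reference`.
#' @param report_empty warn about all-zero rows or columns (default `TRUE`).
#'   Empty nodes are kept, so violations are visible rather than silently
#'   dropped.
#' @return an object of class `bipartite_network`: a list with elements
#'   `incidence` (integer matrix) and `provenance`.
#' @examples
#' m <- matrix(c(1, 1, 0, 1), 2, 2,
#'             dimnames = list(c("A", "B"), c("x", "y")))
#' net <- bipartite_network(m)
#' shift_names(net)
#' @export
bipartite_network <- function(incidence, provenance = NULL,
                              report_empty = TRUE) {
  if (!is.matrix(incidence)) stop("`incidence` must be a matrix")
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("`incidence` must have row (shift) and column (driver) names")
  if (anyDuplicated(rownames(incidence)))
    stop("duplicated shift names: ",
         paste(unique(rownames(incidence)[duplicated(rownames(incidence))]),
               collapse = ", "))
  if (anyDuplicated(colnames(incidence)))
    stop("duplicated driver names: ",
         paste(unique(colnames(incidence)[duplicated(colnames(incidence))]),
               collapse = ", "))
  if (!all(incidence %in% c(0L, 1L)))
    stop("incidence entries must be 0 or 1")
  storage.mode(incidence) <- "integer"
  if (report_empty) {
    er <- rownames(incidence)[rowSums(incidence) == 0]
    ec <- colnames(incidence)[colSums(incidence) == 0]
    if (length(er) || length(ec))
      warning("empty nodes in network: ",
              paste(c(er, ec), collapse = ", "))
  }
  structure(list(incidence = incidence, provenance = provenance),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  m <- x$incidence
  cat(sprintf("bipartite_network: %d regime shifts x %d drivers, %d links\n",
              nrow(m), ncol(m), sum(m)))
  cat(sprintf("mean shift degree %.2f, mean driver degree %.2f\n",
              mean(rowSums(m)), mean(colSums(m))))
  invisible(x)
}

#' @rdname bipartite_network
#' @param x a `bipartite_network`
#' @param ... unused
#' @export
as.matrix.bipartite_network <- function(x, ...) x$incidence

#' @rdname bipartite_network
#' @export
shift_names <- function(x) rownames(as_incidence(x))

#' @rdname bipartite_network
#' @export
driver_names <- function(x) colnames(as_incidence(x))

# Accept either a bipartite_network or a plain named 0/1 matrix everywhere.
as_incidence <- function(x) {
  if (inherits(x, "bipartite_network")) return(x$incidence)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("d", seq_len(ncol(x)))
    storage.mode(x) <- "integer"
    return(x)
  }
  stop("expected a bipartite_network or incidence matrix")
}

#' Read a bipartite network from an edge-list file
#'
#' Reads a delimited file with columns `shift` and `driver` (and optionally
#' `reference`), one record per documented shift-driver link. Duplicate
#' records collapse to a single link; node order is order of first appearance.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param sep field separator; `","` by default, use `"\t"` for TSV.
#' @return a [bipartite_network]. Duplicate-record counts are recorded in
#'   `attr(, "n_duplicate_records")`.
#' @export
read_bipartite_edge_list <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (nrow(df) == 0) stop("empty edge list: ", path)
  if (!all(c("shift", "driver") %in% names(df)))
    stop("edge list must have columns `shift` and `driver`; found: ",
         paste(names(df), collapse = ", "))
  edge_list_to_network(df)
}

# Shared by the reader and the fixture loader.
edge_list_to_network <- function(df) {
  shifts <- unique(df$shift)
  drivers <- unique(df$driver)
  dup <- duplicated(df[c("shift", "driver")])
  m <- matrix(0L, length(shifts), length(drivers),
              dimnames = list(shifts, drivers))
  m[cbind(match(df$shift, shifts), match(df$driver, drivers))] <- 1L
  prov <- NULL
  if ("reference" %in% names(df))
    prov <- df[!dup, c("shift", "driver", "reference")]
  net <- bipartite_network(m, provenance = prov)
  attr(net, "n_duplicate_records") <- sum(dup)
  net
}

#' Write a bipartite network as an edge-list file
#'
#' Inverse of [read_bipartite_edge_list]: one record per link, in row-major
#' (shift-by-shift) order of the incidence matrix, so reading the file back
#' reproduces the network exactly, including node order.
#'
#' @param network a [bipartite_network].
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_bipartite_edge_list <- function(network, path, sep = ",") {
  m <- as_incidence(network)
  idx <- which(t(m) == 1L)  # row-major order over shifts
  df <- data.frame(shift = rownames(m)[(idx - 1) %/% ncol(m) + 1],
                   driver = colnames(m)[(idx - 1) %% ncol(m) + 1],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge synonymous driver names
#'
#' Drivers named inconsistently across sources (spelling variants, case,
#' synonyms such as "cropping" for "agriculture") are merged by logical OR of
#' their link sets under a raw-to-canonical synonym map. Unmapped names pass
#' through unchanged; a canonical name may coincide with an existing driver,
#' in which case the two columns are unioned.
#'
#' @param network a [bipartite_network].
#' @param synonym_map named character vector, `names()` are raw driver labels
#'   and values their canonical labels. The map must be idempotent: no
#'   canonical value may itself be mapped to a different label.
#' @return a [bipartite_network] with merged columns, in order of first
#'   appearance of each canonical name. The merge log (a data frame of
#'   raw/canonical pairs actually applied) is in `attr(, "merge_log")`.
#' @export
canonicalize_driver_names <- function(network, synonym_map) {
  m <- as_incidence(network)
  if (length(synonym_map) == 0) return(network)
  if (is.null(names(synonym_map)))
    stop("`synonym_map` must be a named character vector (raw -> canonical)")
  chained <- intersect(synonym_map, names(synonym_map))
  chained <- chained[synonym_map[chained] != chained]
  if (length(chained))
    stop("synonym map is not idempotent (chain or cycle) via: ",
         paste(chained, collapse = ", "))
  raw <- colnames(m)
  canon <- ifelse(raw %in% names(synonym_map), synonym_map[raw], raw)
  targets <- unique(canon)
  merged <- matrix(0L, nrow(m), length(targets),
                   dimnames = list(rownames(m), targets))
  for (k in seq_along(targets))
    merged[, k] <- as.integer(rowSums(m[, canon == targets[k], drop = FALSE]) > 0)
  log <- data.frame(raw = raw[canon != raw], canonical = canon[canon != raw],
                    row.names = NULL)
  out <- bipartite_network(merged, provenance = network$provenance)
  attr(out, "merge_log") <- log
  out
}

#' Load the in-package worked example network
#'
#' A small curated network of 25 generic regime shift types, each linked to
#' the three selected drivers highlighted in the source database summary,
#' together with the ecosystem type of each shift. This is a strict
#' subnetwork of the full regime shifts database (which records on average
#' about 11 drivers per shift) and is intended as a worked example, not as
#' the full dataset.
#'
#' @param canonical apply the curated synonym map (case folding, ENSO/NSO,
#'   spelling variants) shipped with the fixture? Default `FALSE`, keeping the
#'   raw transcription auditable.
#' @return a list with elements `network` (a [bipartite_network]), `shifts`
#'   (data frame of shift attributes: `node_name`, `side`, `ecosystem`), and
#'   `synonyms` (the curated raw-to-canonical map as a named character
#'   vector).
#' @export
load_table1_fixture <- function(canonical = FALSE) {
  edge_path <- system.file("extdata", "table1_edges.csv", package = "rsdnet",
                           mustWork = TRUE)
  net <- read_bipartite_edge_list(edge_path)
  syn_df <- read.csv(system.file("extdata", "table1_synonyms.csv",
                                 package = "rsdnet", mustWork = TRUE),
                     stringsAsFactors = FALSE)
  synonyms <- stats::setNames(syn_df$canonical, syn_df$raw)
  if (canonical) net <- canonicalize_driver_names(net, synonyms)
  shifts <- read.csv(system.file("extdata", "table1_shifts.csv",
                                 package = "rsdnet", mustWork = TRUE),
                     stringsAsFactors = FALSE)
  shifts <- data.frame(node_name = shifts$shift, side = "shift",
                       ecosystem = shifts$ecosystem,
                       stringsAsFactors = FALSE)
  list(network = net, shifts = shifts, synonyms = synonyms)
}
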