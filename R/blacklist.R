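#' Temporal tier blacklist
#'
#' Builds the set of forbidden arcs implied by measurement order: variables
#' measured later can never be parents of variables measured earlier, and
#' nothing can point into the randomised treatment indicator. Arcs within a
#' tier are permitted in both directions.
#'
#' @param tiers named character vector mapping each variable to one of
#'   `"group"`, `"early"`, `"late"`.
#' @return two-column character matrix (`from`, `to`) of forbidden arcs.
#' @examples
#' tier_blacklist(c(g = "group", e = "early", l = "late"))
#' @export
tier_blacklist <- function(tiers) {
  if (!length(tiers) || is.null(names(tiers))) stop("tiers must be a named vector")
  bad <- setdiff(unique(tiers), c("group", "early", "late"))
  if (length(bad)) stop("unknown tier label(s): ", paste(bad, collapse = ", "))
  rank <- stats::setNames(c(group = 1, early = 2, late = 3)[tiers], names(tiers))
  vars <- names(tiers)
  from <- rep(vars, each = length(vars))
  to <- rep(vars, times = length(vars))
  keep <- from != to & (rank[from] > rank[to] | tiers[to] == "group")
  bl <- cbind(from = from[keep], to = to[keep])
  rownames(bl) <- NULL
  bl
}

# blacklist (2-col matrix or NULL) -> logical p x p matrix F[parent, child],
# with self-arcs always forbidden
blacklist_matrix <- function(blacklist, nodes) {
  F <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  diag(F) <- TRUE
  if (!is.null(blacklist) && NROW(blacklist)) {
    bl <- as.matrix(blacklist)
    keep <- bl[, 1] %in% nodes & bl[, 2] %in% nodes
    if (any(keep)) F[bl[keep, , drop = FALSE]] <- TRUE
  }
  F
}

#' Read / write a blacklist as two-column delimited text
#' @param file path to a tab-separated file with columns `from`, `to`.
#' @return character matrix of forbidden arcs.
#' @export
read_blacklist <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t", colClasses = "character")
  as.matrix(d[, c("from", "to")])
}

#' @rdname read_blacklist
#' @param blacklist two-column matrix of forbidden arcs.
#' @export
write_blacklist <- function(blacklist, file) {
  utils::write.table(as.data.frame(blacklist), file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
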