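#' The 15-tissue table of the finger model
#'
#' Every tissue in the phantom is identified by an integer label 1..15;
#' label 0 is reserved for the ambient medium surrounding the finger.
#' `priority_rank` is the total order used to resolve voxels claimed by more
#' than one tissue mask: rank 1 wins over rank 2 and so on.  The default
#' ranking puts thin or fine structures (vessels, nerves, corpuscles,
#' cartilage, the joint space) first so that structures that are locally only
#' one or two voxels thick are never overwritten by the bulky tissues that
#' surround them; the subcutis, the interior filler, ranks last.
#'
#' Label 13 carries two anatomical names: the synovial membrane is the inner
#' lining of the joint capsule and the model does not separate the two, so
#' "joint capsule" is kept as an alias of the same label.
#'
#' @param priority optional character vector of tissue names giving a custom
#'   priority order (best first); must be a permutation of the 15 names.
#' @return A data.frame with columns `id`, `name`, `alias`, `priority_rank`.
#' @examples
#' tt <- tissue_table()
#' tt[tt$name == "synovial membrane", ]
#' @export
tissue_table <- function(priority = NULL) {
  tab <- data.frame(
    id = 1:15,
    name = c("subcutis", "Pacinian corpuscle", "nerve", "vein", "artery",
             "tendon", "collateral ligament", "volar plate", "pulley A4",
             "bone", "cartilage", "synovial cavity", "synovial membrane",
             "epidermis", "dermis"),
    alias = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
              "joint capsule", NA, NA),
    stringsAsFactors = FALSE
  )
  default_order <- c("artery", "vein", "nerve", "Pacinian corpuscle",
                     "cartilage", "synovial cavity", "synovial membrane",
                     "pulley A4", "collateral ligament", "volar plate",
                     "tendon", "bone", "epidermis", "dermis", "subcutis")
  ord <- if (is.null(priority)) default_order else priority
  if (!setequal(ord, tab$name) || length(ord) != 15L)
    stop("priority must be a permutation of the 15 tissue names")
  tab$priority_rank <- match(tab$name, ord)
  validate_tissue_table(tab)
  tab
}

#' Validate a tissue table
#'
#' Checks the structural invariants: exactly 15 entries, unique contiguous
#' ids 1..15, and a unique total priority order.
#'
#' @param table a data.frame as returned by [tissue_table()].
#' @return The table, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_tissue_table <- function(table) {
  stopifnot(is.data.frame(table))
  if (!all(c("id", "name", "priority_rank") %in% names(table)))
    stop("tissue table needs columns id, name, priority_rank")
  if (nrow(table) != 15L || !identical(sort(table$id), 1:15))
    stop("tissue table must have exactly 15 entries with ids 1..15")
  if (anyDuplicated(table$priority_rank) || anyDuplicated(table$name))
    stop("priority ranks and names must be unique")
  invisible(table)
}

#' Look up a tissue id by name or alias
#'
#' @param name tissue name (or alias, e.g. "joint capsule").
#' @param table a tissue table; defaults to [tissue_table()].
#' @return integer label id.
#' @export
tissue_id <- function(name, table = tissue_table()) {
  i <- match(name, table$name)
  if (is.na(i)) i <- match(name, table$alias)
  if (is.na(i)) stop("unknown tissue: ", name)
  table$id[i]
}
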