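#' Read a 6-column PED pedigree file
#'
#' Columns: family, individual id, sire id, dam id, sex (1 = male,
#' 2 = female, 0 = unknown), phenotype (2 = affected, 1 = unaffected,
#' 0/-9 = unknown). Parent code "0" maps to unknown. Roles are inferred:
#' affected individuals are cases, parents of a case are parents, everyone
#' else is a control. Designs with two or more affected offspring sharing a
#' sire whose dams are absent are flagged as paternal half-sib designs.
#'
#' @param path path to a whitespace-delimited PED file.
#' @return a data.frame of class `pedigree` with columns `family`, `id`,
#'   `sire`, `dam`, `sex`, `affected`, `role`, `tissue` and an attribute
#'   `half_sib_design`.
#' @export
read_ped <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 6) stop("PED file must have at least 6 columns")
  ped <- data.frame(
    family = raw[[1]], id = raw[[2]],
    sire = ifelse(raw[[3]] == "0", NA_character_, raw[[3]]),
    dam = ifelse(raw[[4]] == "0", NA_character_, raw[[4]]),
    sex = c("0" = "unknown", "1" = "male", "2" = "female")[raw[[5]]],
    affected = raw[[6]] == "2",
    stringsAsFactors = FALSE)
  ped$sex[is.na(ped$sex)] <- "unknown"
  ped$tissue <- "unknown"
  as_pedigree(ped)
}

#' Build a validated pedigree from a data.frame
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`, `sex`, `affected`
#'   (and optionally `family`, `tissue`).
#' @return the validated `pedigree` with inferred `role` column.
#' @export
as_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) {
    stop("duplicated individual id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  if (!("family" %in% names(ped))) ped$family <- "F1"
  if (!("tissue" %in% names(ped))) ped$tissue <- "unknown"
  check_pedigree_acyclic(ped)
  sires <- stats::na.omit(unique(ped$sire))
  dams <- stats::na.omit(unique(ped$dam))
  if (any(ped$sex[ped$id %in% sires] == "female")) {
    stop("a recorded sire has female sex")
  }
  if (any(ped$sex[ped$id %in% dams] == "male")) {
    stop("a recorded dam has male sex")
  }
  case_ids <- ped$id[ped$affected]
  parent_ids <- unique(c(ped$sire[ped$id %in% case_ids],
                         ped$dam[ped$id %in% case_ids]))
  ped$role <- ifelse(ped$affected, "case",
                     ifelse(ped$id %in% parent_ids, "parent", "control"))
  # paternal half-sib design: >= 2 cases sharing a sire, dams unrecorded
  cases <- ped[ped$affected, , drop = FALSE]
  hs <- FALSE
  if (nrow(cases) >= 2) {
    by_sire <- split(cases, cases$sire)
    hs <- any(vapply(by_sire, function(g) {
      nrow(g) >= 2 && all(is.na(g$dam))
    }, logical(1)))
  }
  attr(ped, "half_sib_design") <- hs
  class(ped) <- c("pedigree", "data.frame")
  ped
}

check_pedigree_acyclic <- function(ped) {
  # walk ancestors of every individual; a revisit of self means a cycle
  up <- function(id) unname(c(ped$sire[ped$id == id], ped$dam[ped$id == id]))
  for (id in ped$id) {
    frontier <- stats::na.omit(up(id))
    seen <- character(0)
    while (length(frontier)) {
      if (id %in% frontier) {
        stop("cyclic pedigree: ", id, " is its own ancestor")
      }
      seen <- union(seen, frontier)
      frontier <- setdiff(
        stats::na.omit(unlist(lapply(intersect(frontier, ped$id), up))), seen)
    }
  }
  invisible(TRUE)
}

#' Write a pedigree in 6-column PED format
#'
#' @param ped a `pedigree` (see [read_ped()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  sex_code <- c(male = "1", female = "2", unknown = "0")
  out <- data.frame(ped$family, ped$id,
                    ifelse(is.na(ped$sire), "0", ped$sire),
                    ifelse(is.na(ped$dam), "0", ped$dam),
                    sex_code[ped$sex],
                    ifelse(ped$affected, "2", "1"))
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}
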