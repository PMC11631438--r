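# Pedigree handling: a validated tibble of individuals with parent links.

#' Build a pedigree from a tibble of individuals
#'
#' @param individuals Tibble/data frame with columns `id`, `sex`
#'   (`"male"`, `"female"` or `"unknown"`), `mother_id`, `father_id`
#'   (`NA` when unknown), and optionally `sequenced` (logical, default `TRUE`)
#'   and `carrier_status` (`"biallelic"`, `"monoallelic"`, `"noncarrier"` or
#'   `"unknown"`, default `"unknown"`).
#' @return A `kin_pedigree` tibble.
#' @details Validation rejects duplicate ids, parent links to unlisted
#'   individuals, and cyclic parentage. Full siblings are individuals sharing
#'   both (non-missing) parent ids; see [full_siblings()].
#' @export
pedigree <- function(individuals) {
  x <- as_tibble(individuals)
  stopifnot(all(c("id", "sex", "mother_id", "father_id") %in% names(x)))
  if (!"sequenced" %in% names(x)) x$sequenced <- TRUE
  if (!"carrier_status" %in% names(x)) x$carrier_status <- "unknown"
  x <- x[, c("id", "sex", "mother_id", "father_id", "sequenced", "carrier_status")]
  if (anyDuplicated(x$id)) {
    abort(paste0("duplicate individual id(s): ",
                 paste(unique(x$id[duplicated(x$id)]), collapse = ", ")))
  }
  if (!all(x$sex %in% c("male", "female", "unknown"))) {
    abort("sex must be one of 'male', 'female', 'unknown'")
  }
  for (col in c("mother_id", "father_id")) {
    ref <- x[[col]]
    bad <- !is.na(ref) & !(ref %in% x$id)
    if (any(bad)) {
      abort(paste0(col, " references undefined individual(s): ",
                   paste(unique(ref[bad]), collapse = ", ")))
    }
  }
  check_acyclic(x)
  class(x) <- c("kin_pedigree", class(x))
  x
}

check_acyclic <- function(x) {
  # depth-first walk up parent links from every individual
  parent_of <- function(id) {
    row <- x[x$id == id, ]
    c(row$mother_id, row$father_id)
  }
  for (start in x$id) {
    stack <- start
    seen <- character()
    while (length(stack) > 0) {
      cur <- stack[[1]]
      stack <- stack[-1]
      if (cur %in% seen) next
      seen <- c(seen, cur)
      for (p in parent_of(cur)) {
        if (is.na(p)) next
        if (p == start) abort(paste0("cyclic parentage involving '", start, "'"))
        stack <- c(stack, p)
      }
    }
  }
  invisible(x)
}

#' Read a 6-column PED pedigree file
#'
#' Standard PED columns: family id, individual id, father id, mother id,
#' sex (1 = male, 2 = female, other = unknown), phenotype (ignored).
#' A parent id of `"0"` means the parent is absent.
#'
#' @param path Path to a whitespace-delimited PED file.
#' @return A `kin_pedigree` tibble.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "id", "father", "mother",
                                         "sex", "phenotype"))
  raw$id <- as.character(raw$id)
  raw$father <- as.character(raw$father)
  raw$mother <- as.character(raw$mother)
  sex <- dplyr::case_when(
    raw$sex == 1 ~ "male",
    raw$sex == 2 ~ "female",
    TRUE ~ "unknown"
  )
  pedigree(tibble(
    id = raw$id,
    sex = sex,
    mother_id = if_else(raw$mother == "0", NA_character_, raw$mother),
    father_id = if_else(raw$father == "0", NA_character_, raw$father),
    sequenced = TRUE,
    carrier_status = "unknown"
  ))
}

#' Write a pedigree as a 6-column PED file
#' @param ped A `kin_pedigree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    fid = "FAM1",
    id = ped$id,
    father = if_else(is.na(ped$father_id), "0", ped$father_id),
    mother = if_else(is.na(ped$mother_id), "0", ped$mother_id),
    sex = c(male = 1L, female = 2L, unknown = 0L)[ped$sex],
    phenotype = -9L
  )
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Full-sibling sets of a pedigree
#'
#' @param ped A `kin_pedigree`.
#' @return A list of character vectors, one per sibship of size >= 2 whose
#'   members share both parent ids.
#' @export
full_siblings <- function(ped) {
  kids <- ped[!is.na(ped$mother_id) & !is.na(ped$father_id), ]
  if (nrow(kids) == 0) return(list())
  key <- paste(kids$mother_id, kids$father_id, sep = "\r")
  sets <- split(kids$id, key)
  unname(keep(sets, ~ length(.x) >= 2))
}

# TRUE iff a and b are in a direct parent-child relationship.
is_parent_child <- function(ped, a, b) {
  ra <- ped[ped$id == a, ]
  rb <- ped[ped$id == b, ]
  if (nrow(ra) == 0 || nrow(rb) == 0) return(FALSE)
  isTRUE(ra$mother_id == b) || isTRUE(ra$father_id == b) ||
    isTRUE(rb$mother_id == a) || isTRUE(rb$father_id == a)
}
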