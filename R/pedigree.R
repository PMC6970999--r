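# Trio pedigree: the lens through which all genotype rules are evaluated.

#' Construct a trio pedigree
#'
#' @param proband_id,mother_id,father_id distinct sample identifiers matching
#'   the VCF sample columns.
#' @param proband_sex `"MALE"` or `"FEMALE"`; required because hemizygous
#'   chrX logic depends on it.
#' @param affected named logical vector for `proband`, `mother`, `father`.
#'   The analysis expects an affected proband with unaffected parents and
#'   warns otherwise.
#' @return an object of class `trio_pedigree`.
#' @export
trio_pedigree <- function(proband_id, mother_id, father_id,
                          proband_sex = c("MALE", "FEMALE"),
                          affected = c(proband = TRUE, mother = FALSE, father = FALSE)) {
  proband_sex <- match.arg(proband_sex)
  ids <- c(proband_id, mother_id, father_id)
  if (anyDuplicated(ids)) stop("pedigree sample identifiers must be distinct")
  affected <- affected[c("proband", "mother", "father")]
  if (anyNA(affected)) stop("affected status must name proband, mother and father")
  if (!affected[["proband"]] || affected[["mother"]] || affected[["father"]]) {
    warning("expected an affected proband with unaffected parents; ",
            "inheritance-mode rules assume this pedigree structure")
  }
  structure(
    list(proband_id = proband_id, mother_id = mother_id, father_id = father_id,
         proband_sex = proband_sex, affected = affected),
    class = "trio_pedigree"
  )
}

#' @export
print.trio_pedigree <- function(x, ...) {
  cat("Trio pedigree\n")
  cat("  proband:", x$proband_id, sprintf("(%s, %s)", x$proband_sex,
      if (x$affected[["proband"]]) "affected" else "unaffected"), "\n")
  cat("  mother: ", x$mother_id, "\n")
  cat("  father: ", x$father_id, "\n")
  invisible(x)
}

#' Read a 6-column PED file into a trio pedigree
#'
#' Expects the classic PED dialect (family, individual, father, mother, sex,
#' phenotype; sex 1 = male, 2 = female; phenotype 2 = affected). Exactly one
#' affected individual with both declared parents present in the file must
#' exist; line order is irrelevant.
#'
#' @param path PED file path. Lines starting with `#` are ignored.
#' @return a [trio_pedigree()].
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("PED file is empty: ", path)
  ped <- fread(text = lines, header = FALSE, colClasses = "character")
  if (ncol(ped) < 6L) stop("PED file must have 6 columns, found ", ncol(ped))
  setnames(ped, 1:6, c("family", "id", "father", "mother", "sex", "phenotype"))

  is_child <- ped$phenotype == "2" & ped$father != "0" & ped$mother != "0" &
    ped$father %in% ped$id & ped$mother %in% ped$id
  if (sum(is_child) == 0L) {
    stop("PED file declares no affected individual with both parents present")
  }
  if (sum(is_child) > 1L) {
    stop("PED file declares ", sum(is_child),
         " affected trios; exactly one is required")
  }
  child <- ped[which(is_child)]
  if (!child$sex %in% c("1", "2")) {
    stop("proband sex code must be 1 (male) or 2 (female); chrX logic ",
         "requires a known proband sex")
  }
  pheno <- function(id) ped$phenotype[match(id, ped$id)] == "2"
  trio_pedigree(
    proband_id = child$id,
    mother_id = child$mother,
    father_id = child$father,
    proband_sex = if (child$sex == "1") "MALE" else "FEMALE",
    affected = c(proband = TRUE,
                 mother = isTRUE(pheno(child$mother)),
                 father = isTRUE(pheno(child$father)))
  )
}
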