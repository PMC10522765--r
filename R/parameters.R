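#' Read a flat parameter table
#'
#' The table is whitespace-separated text with one record per
#' (residue name, atom name) pair and columns
#' `resname atom mass charge sigma epsilon` (amu, e, A, kcal/mol).
#' Lines starting with `#` are comments.
#'
#' @param path Path to the parameter file.
#' @return A tibble with the five columns above.
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("resname", "atom", "mass", "charge", "sigma", "epsilon")
  if (!all(need %in% names(tab))) {
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  }
  tab$resname <- normalize_resname(tab$resname)
  tab$atom <- normalize_atom_name(tab$atom)
  tibble::as_tibble(tab[need])
}

#' Assign masses, charges and Lennard-Jones parameters to a system
#'
#' Every atom is looked up by (residue name, atom name) in the table; atoms
#' without an entry are collected and reported in a single aggregated error,
#' so one run surfaces the complete list of missing parameters.
#'
#' @param system A [mol_system].
#' @param table A parameter table (tibble from [read_parameter_table()]) or a
#'   file path.
#' @return The system with `mass`, `charge`, `lj_sigma`, `lj_epsilon` filled.
#' @export
load_parameters <- function(system, table) {
  if (is.character(table)) table <- read_parameter_table(table)
  a <- system$atoms
  key  <- paste(normalize_resname(a$resname), a$name)
  tkey <- paste(table$resname, table$atom)
  hit <- match(key, tkey)
  if (anyNA(hit)) {
    miss <- unique(paste(normalize_resname(a$resname), a$name)[is.na(hit)])
    stop("unparameterized atoms (residue atom): ",
         paste(miss, collapse = "; "))
  }
  a$mass       <- table$mass[hit]
  a$charge     <- table$charge[hit]
  a$lj_sigma   <- table$sigma[hit]
  a$lj_epsilon <- table$epsilon[hit]
  if (any(a$mass <= 0)) stop("parameter table contains non-positive masses")
  system$atoms <- a
  system
}

#' Write a parameter table
#' @param table Tibble with columns `resname atom mass charge sigma epsilon`.
#' @param path Output path.
#' @export
write_parameter_table <- function(table, path) {
  utils::write.table(table, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
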