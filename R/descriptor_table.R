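#' Descriptor table
#'
#' Long-format store of per-species reactivity descriptors: condensed Fukui
#' triples per atom label, ELF disynaptic-basin electron populations per
#' bond label (only C-O and C-C bonds are exported), and gross IGM pair
#' indices per pair label. Atom labels follow the pyranose ring convention:
#' ring carbons `C1`..`C5` (C1 anomeric), ring oxygen `O`, hydroxyl oxygens
#' `O1`..`O4` numbered by carbon, hydroxyl protons `H_O1`.., carbon protons
#' `H1`... Bond labels are `V(A,B)` strings; pair labels `A-B`.
#'
#' @param rows optional data.frame with columns `species`, `record`
#'   (`"fukui"`, `"bond"`, `"pair"`), `label`, `f_plus`, `f_minus`,
#'   `f_zero`, `value`.
#' @return object of class `descriptor_table` (a data.frame).
#' @export
descriptor_table <- function(rows = NULL) {
  template <- data.frame(species = character(), record = character(),
                         label = character(), f_plus = numeric(),
                         f_minus = numeric(), f_zero = numeric(),
                         value = numeric(), stringsAsFactors = FALSE)
  if (is.null(rows)) rows <- template
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(template), names(rows))
  for (cc in missing_cols) rows[[cc]] <- rep(NA_real_, nrow(rows))
  rows <- rows[names(template)]
  key <- paste(rows$species, rows$record, rows$label)
  if (anyDuplicated(key))
    stop("duplicate descriptor keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  class(rows) <- c("descriptor_table", "data.frame")
  rows
}

#' Append Fukui rows to a descriptor table
#'
#' @param table a `descriptor_table`.
#' @param species species id.
#' @param labels atom labels (e.g. `"C1"`, `"O2"`).
#' @param fukui a [condensed_fukui()] data.frame (or one with the same
#'   columns), rows matching `labels`.
#' @export
add_fukui_rows <- function(table, species, labels, fukui) {
  stopifnot(length(labels) == nrow(fukui))
  descriptor_table(rbind(
    as.data.frame(table),
    data.frame(species = species, record = "fukui", label = labels,
               f_plus = fukui$f_plus, f_minus = fukui$f_minus,
               f_zero = fukui$f_zero, value = NA_real_,
               stringsAsFactors = FALSE)))
}

#' Append ELF bond-population rows
#' @param table a `descriptor_table`.
#' @param species species id.
#' @param labels bond labels (e.g. `"V(C1,O)"`).
#' @param populations electron populations (e).
#' @export
add_bond_rows <- function(table, species, labels, populations) {
  stopifnot(length(labels) == length(populations))
  descriptor_table(rbind(
    as.data.frame(table),
    data.frame(species = species, record = "bond", label = labels,
               f_plus = NA_real_, f_minus = NA_real_, f_zero = NA_real_,
               value = as.numeric(populations), stringsAsFactors = FALSE)))
}

#' Append IGM pair-index rows
#' @param table a `descriptor_table`.
#' @param species species id.
#' @param labels pair labels (e.g. `"C1-O"`, `"O1-H_O1"`).
#' @param values gross pair indices (dimensionless).
#' @export
add_pair_rows <- function(table, species, labels, values) {
  stopifnot(length(labels) == length(values))
  descriptor_table(rbind(
    as.data.frame(table),
    data.frame(species = species, record = "pair", label = labels,
               f_plus = NA_real_, f_minus = NA_real_, f_zero = NA_real_,
               value = as.numeric(values), stringsAsFactors = FALSE)))
}

#' Write / read a descriptor table as tab-delimited text
#' @param table a `descriptor_table`.
#' @param path file path.
#' @export
write_descriptor_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  descriptor_table(utils::read.delim(path, stringsAsFactors = FALSE))
}
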