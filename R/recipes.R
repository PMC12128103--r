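# elimination site lists, positions i = 1..7: which carbons carry f0, which
# hydroxyl oxygen carries f-, the C-O bond whose ELF population enters, and
# the two IGM pairs (leaving C-O linkage + migrating C-H)
.elim_rules <- list(
  list(c_sites = c("C1", "C2"), o_site = "O1", bond_c = "C1", bond_o = "O1",
       h_pair = c("C2", "H2")),
  list(c_sites = c("C2", "C1"), o_site = "O2", bond_c = "C2", bond_o = "O2",
       h_pair = c("C1", "H1")),
  list(c_sites = c("C3", "C2"), o_site = "O2", bond_c = "C2", bond_o = "O2",
       h_pair = c("C3", "H3")),
  list(c_sites = c("C3", "C2"), o_site = "O3", bond_c = "C3", bond_o = "O3",
       h_pair = c("C2", "H2")),
  list(c_sites = c("C4", "C3"), o_site = "O3", bond_c = "C3", bond_o = "O3",
       h_pair = c("C4", "H4")),
  list(c_sites = c("C4", "C3"), o_site = "O4", bond_c = "C4", bond_o = "O4",
       h_pair = c("C4", "H4")),
  list(c_sites = c("C5", "C4"), o_site = "O4", bond_c = "C4", bond_o = "O4",
       h_pair = c("C5", "H5"))
)

pair_label <- function(a, b) paste0(a, "-", b)
bond_label <- function(a, b) paste0("V(", a, ",", b, ")")

# substituent carbon attached to hydroxyl oxygen O<pos>
substituent_carbon <- function(group, pos) {
  switch(group, acetyl = paste0("Cac", pos), methoxy = paste0("Cme", pos),
         stop("no oxygen-linked carbon for group ", group))
}

#' Build a reaction-class descriptor recipe
#'
#' Returns the site, bond and pair label lists whose tabulated descriptor
#' values are averaged into the EPL inputs for one elementary reaction of a
#' (possibly functionalized) xylopyranose:
#' * `ring_opening` (acyclic sugar formation): Fukui sites
#'   `{C1: f0, O: f-, O1: f-}`, bond `V(C1,O)`, pairs `C1-O` and `O1-H_O1`.
#' * `ring_contraction_FF1` (furanic channel via C2-C3 and C1-O1 scission):
#'   five Fukui sites, bond `V(C1,O1)`, three pairs.
#' * `ring_contraction_FF2` (via C1-O and C2-O2 scission): five Fukui
#'   sites, bonds `V(C1,O)` and `V(C2,O2)`, three pairs.
#' * `elimination` at position `i` in 1..7 (anhydro-sugar formation):
#'   three Fukui sites, one C-O bond and two pairs per the positional rules.
#'
#' When the hydroxyl oxygen a recipe consumes carries a substituent
#' (acetyl at 2/3, methoxy at 4), the proton-transfer pair `Oi-H_Oi` is
#' relabeled to the leaving-group linkage `Oi-C<group><i>` (the oxygen's
#' actual bonded partner) and a warning is emitted; a carboxyl at position 5
#' touching a recipe's C5/H5 sites also warns.
#'
#' @param class one of `"ring_opening"`, `"ring_contraction_FF1"`,
#'   `"ring_contraction_FF2"`, `"elimination"`.
#' @param position elimination position i (1..7); ignored otherwise.
#' @param substitutions named character vector mapping ring position to
#'   group, e.g. `c("2" = "acetyl", "4" = "methoxy", "5" = "carboxyl")`.
#' @return object of class `reaction_recipe`: list with `class`,
#'   `fukui_sites` (data.frame `label`, `kind` in `f0`/`f-`), `bonds`
#'   (character) and `pairs` (character).
#' @export
build_recipe <- function(class = c("ring_opening", "ring_contraction_FF1",
                                   "ring_contraction_FF2", "elimination"),
                         position = NULL, substitutions = NULL) {
  class <- match.arg(class)
  if (!is.null(substitutions)) {
    ok <- (substitutions == "acetyl" & names(substitutions) %in% c("2", "3")) |
      (substitutions == "methoxy" & names(substitutions) == "4") |
      (substitutions == "carboxyl" & names(substitutions) == "5")
    if (!all(ok))
      stop("illegal substitution: acetyl at 2/3, methoxy at 4, carboxyl at 5")
  }
  rec <- switch(class,
    ring_opening = list(
      fukui_sites = data.frame(label = c("C1", "O", "O1"),
                               kind = c("f0", "f-", "f-")),
      bonds = bond_label("C1", "O"),
      pairs = c(pair_label("C1", "O"), pair_label("O1", "H_O1"))),
    ring_contraction_FF1 = list(
      fukui_sites = data.frame(label = c("C1", "C2", "C3", "O1", "O2"),
                               kind = c("f0", "f0", "f0", "f-", "f-")),
      bonds = bond_label("C1", "O1"),
      pairs = c(pair_label("C2", "C3"), pair_label("C1", "O1"),
                pair_label("O2", "H_O2"))),
    ring_contraction_FF2 = list(
      fukui_sites = data.frame(label = c("C1", "C2", "O", "O1", "O2"),
                               kind = c("f0", "f0", "f-", "f-", "f-")),
      bonds = c(bond_label("C1", "O"), bond_label("C2", "O2")),
      pairs = c(pair_label("C1", "O"), pair_label("C2", "O2"),
                pair_label("O1", "H_O1"))),
    elimination = {
      if (is.null(position) || !(position %in% 1:7))
        stop("elimination position must be an integer in 1..7")
      r <- .elim_rules[[position]]
      list(
        fukui_sites = data.frame(label = c(r$c_sites, r$o_site),
                                 kind = c("f0", "f0", "f-")),
        bonds = bond_label(r$bond_c, r$bond_o),
        pairs = c(pair_label(r$bond_c, r$bond_o),
                  pair_label(r$h_pair[1], r$h_pair[2])))
    })
  # leaving-group-aware relabeling for substituted hydroxyl positions
  for (pos in names(substitutions)) {
    group <- substitutions[[pos]]
    if (group == "carboxyl") {
      touched <- c("C5", "H5") %in%
        c(rec$fukui_sites$label, unlist(strsplit(rec$pairs, "-")))
      if (any(touched))
        warning("recipe touches C5/H5 while position 5 bears a carboxyl; ",
                "site labels kept, review the leaving group")
      next
    }
    o_lab <- paste0("O", pos)
    oh_pair <- pair_label(o_lab, paste0("H_", o_lab))
    if (oh_pair %in% rec$pairs) {
      new_pair <- pair_label(o_lab, substituent_carbon(group, pos))
      rec$pairs[rec$pairs == oh_pair] <- new_pair
      warning(sprintf(
        "position %s bears %s: proton-transfer pair %s relabeled to the leaving-group linkage %s",
        pos, group, oh_pair, new_pair))
    } else if (o_lab %in% rec$fukui_sites$label) {
      warning(sprintf(
        "f- site %s is the %s linkage oxygen of the substituted position",
        o_lab, group))
    }
  }
  structure(c(list(class = class, position = position), rec),
            class = "reaction_recipe")
}

#' @export
print.reaction_recipe <- function(x, ...) {
  cat("recipe:", x$class,
      if (!is.null(x$position)) paste0("(i = ", x$position, ")"), "\n")
  cat("  fukui sites:",
      paste(sprintf("%s:%s", x$fukui_sites$label, x$fukui_sites$kind),
            collapse = ", "), "\n")
  cat("  bonds:", paste(x$bonds, collapse = ", "), "\n")
  cat("  pairs:", paste(x$pairs, collapse = ", "), "\n")
  invisible(x)
}

lookup_rows <- function(table, species, record, labels) {
  idx <- match(paste(species, record, labels),
               paste(table$species, table$record, table$label))
  if (anyNA(idx))
    stop("descriptor table is missing ", record, " label(s): ",
         paste(labels[is.na(idx)], collapse = ", "),
         " for species '", species, "'")
  table[idx, , drop = FALSE]
}

#' Aggregate descriptors for a reaction recipe
#'
#' Arithmetic means over the recipe's label lists: `f_bar` averages the
#' listed condensed Fukui values (each with its listed kind, `f0` or `f-`),
#' `n_bar` averages the listed disynaptic-bond electron populations, and
#' `g_bar` averages the listed gross IGM pair indices.
#'
#' @param recipe a [build_recipe()] result.
#' @param table a [descriptor_table()].
#' @param species species id to look up.
#' @return object of class `aggregate_descriptors`: list with `f_bar`,
#'   `n_bar`, `g_bar`.
#' @export
aggregate_descriptors <- function(recipe, table, species) {
  fk <- lookup_rows(table, species, "fukui", recipe$fukui_sites$label)
  fvals <- ifelse(recipe$fukui_sites$kind == "f0", fk$f_zero, fk$f_minus)
  if (anyNA(fvals))
    stop("missing Fukui component for site(s): ",
         paste(recipe$fukui_sites$label[is.na(fvals)], collapse = ", "))
  bd <- lookup_rows(table, species, "bond", recipe$bonds)
  pr <- lookup_rows(table, species, "pair", recipe$pairs)
  structure(list(f_bar = mean(fvals), n_bar = mean(bd$value),
                 g_bar = mean(pr$value)),
            class = "aggregate_descriptors")
}

#' @export
print.aggregate_descriptors <- function(x, ...) {
  cat(sprintf("f_bar = %.4f, n_bar = %.4f e, g_bar = %.4f\n",
              x$f_bar, x$n_bar, x$g_bar))
  invisible(x)
}
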