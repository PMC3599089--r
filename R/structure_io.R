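#' Default van der Waals radius table
#'
#' A Bondi-style hard-sphere radius set (Angstrom) covering the elements
#' common in protein structures plus frequent hetero elements.  Shipped as
#' a plain two-column file under `extdata/vdw_radii.tsv` so it can be
#' inspected, replaced, or overridden per element.
#'
#' @param path Optional path to an alternative two-column (element, radius)
#'   tab-separated file.
#' @return Named numeric vector, element symbol -> radius in Angstrom.
#' @export
#' @examples
#' vdw_radii_default()[["C"]]  # 1.70
vdw_radii_default <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vdw_radii.tsv", package = "voxpocket",
                        mustWork = TRUE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$radius), tab$element)
}

# Derive an element symbol from the raw 4-character PDB atom-name field.
# Two-letter elements (FE, ZN, ...) start in column 13; standard organic
# atoms are indented by one blank.
derive_element <- function(name4, known) {
  name4 <- formatC(name4, width = 4, flag = "-")
  two <- toupper(gsub("[^A-Za-z]", "", substr(name4, 1, 2)))
  first_nonblank <- substr(trimws(name4), 1, 1)
  out <- character(length(name4))
  starts_col13 <- substr(name4, 1, 1) != " "
  two_known <- two %in% toupper(known) & nchar(two) == 2
  use_two <- starts_col13 & two_known
  out[use_two] <- two[use_two]
  rest <- !use_two
  out[rest] <- toupper(gsub("[^A-Za-z]", "", first_nonblank[rest]))
  # normalize case: first upper, second lower
  paste0(substr(out, 1, 1), tolower(substr(out, 2, 2)))
}

parse_atom_records <- function(lines) {
  n <- length(lines)
  num <- function(a, b) as.numeric(substr(lines, a, b))
  int <- function(a, b) suppressWarnings(as.integer(substr(lines, a, b)))
  data.frame(
    serial  = int(7, 11),
    name    = substr(lines, 13, 16),
    altloc  = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain   = substr(lines, 22, 22),
    resseq  = int(23, 26),
    icode   = substr(lines, 27, 27),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
}

# Keep the first alternate location of each atom: blank altloc always kept;
# otherwise the first record seen for a (chain, resseq, icode, name) key.
filter_altloc <- function(df) {
  if (nrow(df) == 0L) return(df)
  blank <- df$altloc %in% c(" ", "")
  key <- paste(df$chain, df$resseq, df$icode, df$name)
  keep <- blank | !duplicated(key)
  df[keep & (blank | !key %in% key[blank]), , drop = FALSE]
}

#' Parse a PDB file into a structure object
#'
#' Reads fixed-width `ATOM` and `HETATM` records (wwPDB column layout).
#' Only the first model of a multi-model (NMR) file is used, and only the
#' first alternate location of each atom is kept.  `HETATM` records
#' (ligands, waters, ions) are excluded from the protein body but retained
#' in the `het` slot for ligand-derived binding-site annotation.
#'
#' @param path Path to a PDB file.
#' @param chains Optional character vector of chain identifiers to keep;
#'   `NULL` keeps all chains.  A requested chain absent from the file is an
#'   error.
#' @param radii Radius table used by [assign_radii()]; pass `NULL` to skip
#'   radius assignment.
#' @param fallback Fallback radius (Angstrom) for unknown elements.
#' @return An object of class `pdb_structure`: a list with `atoms` and
#'   `het` data frames (columns serial, name, altloc, resname, chain,
#'   resseq, icode, x, y, z, element, radius), `source_id`, and
#'   `selected_chains`.
#' @export
parse_pdb <- function(path, chains = NULL, radii = vdw_radii_default(),
                      fallback = 1.5) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1L] - 1L)]
  rec <- substr(lines, 1, 6)
  atoms <- parse_atom_records(lines[rec == "ATOM  "])
  het <- parse_atom_records(lines[rec == "HETATM"])
  if (nrow(atoms) == 0L) {
    stop("no ATOM records found in '", path, "'")
  }
  atoms <- filter_altloc(atoms)
  het <- filter_altloc(het)
  if (!is.null(chains)) {
    chains <- as.character(chains)
    missing <- setdiff(chains, unique(atoms$chain))
    if (length(missing) > 0L) {
      stop("chain(s) not found in '", path, "': ",
           paste(missing, collapse = ", "))
    }
    atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
    het <- het[het$chain %in% chains, , drop = FALSE]
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates in '", path, "'")
  }
  s <- structure(
    list(atoms = atoms, het = het, source_id = basename(path),
         selected_chains = chains),
    class = "pdb_structure"
  )
  if (!is.null(radii)) s <- assign_radii(s, radii, fallback) else {
    s$atoms$radius <- NA_real_
    if (nrow(s$het)) s$het$radius <- NA_real_
  }
  s
}

#' Assign van der Waals radii to a structure
#'
#' Resolves every atom's element (from the element column when present,
#' otherwise from the atom-name field) and assigns its radius from the
#' table.  Unknown elements receive `fallback` with one warning per
#' distinct unknown element.
#'
#' @param structure A `pdb_structure`.
#' @param table Named numeric vector element -> radius (Angstrom); entries
#'   override [vdw_radii_default()] when merged by name.
#' @param fallback Radius for elements absent from the table.
#' @return The structure with `radius` filled in on `atoms` and `het`.
#' @export
assign_radii <- function(structure, table = vdw_radii_default(),
                         fallback = 1.5) {
  stopifnot(inherits(structure, "pdb_structure"), all(table > 0),
            fallback > 0)
  fill <- function(df) {
    if (nrow(df) == 0L) { df$radius <- numeric(0); return(df) }
    el <- df$element
    need <- is.na(el) | el == ""
    if (any(need)) el[need] <- derive_element(df$name[need], names(table))
    el_norm <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 3)))
    r <- unname(table[el_norm])
    unknown <- is.na(r)
    if (any(unknown)) {
      for (u in unique(el_norm[unknown])) {
        warning("unknown element '", u, "': using fallback radius ",
                fallback, " Angstrom", call. = FALSE)
      }
      r[unknown] <- fallback
    }
    df$element <- el_norm
    df$radius <- r
    df
  }
  structure$atoms <- fill(structure$atoms)
  structure$het <- fill(structure$het)
  structure
}

#' Select chains from a structure
#'
#' @param structure A `pdb_structure`.
#' @param chains Character vector of chain ids to keep.
#' @return The filtered structure (idempotent, order-preserving).
#' @export
select_chains <- function(structure, chains) {
  stopifnot(inherits(structure, "pdb_structure"))
  chains <- as.character(chains)
  missing <- setdiff(chains, unique(structure$atoms$chain))
  if (length(missing) > 0L) {
    stop("chain(s) not found: ", paste(missing, collapse = ", "))
  }
  structure$atoms <- structure$atoms[structure$atoms$chain %in% chains, ,
                                     drop = FALSE]
  structure$het <- structure$het[structure$het$chain %in% chains, ,
                                 drop = FALSE]
  structure$selected_chains <- chains
  structure
}

#' Write a structure back to PDB format
#'
#' @param structure A `pdb_structure`.
#' @param path Output file; when `NULL` the lines are returned invisibly
#'   without writing.
#' @param bfactor Optional numeric vector (one per protein atom) written to
#'   the B-factor column, e.g. per-atom mean solid angles from
#'   [solid_angle_to_bfactor()].
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_pdb <- function(structure, path = NULL, bfactor = NULL) {
  stopifnot(inherits(structure, "pdb_structure"))
  fmt <- function(df, rectype, b) {
    if (nrow(df) == 0L) return(character(0))
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rectype, df$serial, df$name, df$altloc, df$resname, df$chain,
            df$resseq, df$icode, df$x, df$y, df$z, 1, b,
            toupper(df$element))
  }
  b_at <- if (is.null(bfactor)) rep(0, nrow(structure$atoms)) else bfactor
  stopifnot(length(b_at) == nrow(structure$atoms))
  lines <- c(fmt(structure$atoms, "ATOM", b_at),
             fmt(structure$het, "HETATM", rep(0, nrow(structure$het))),
             "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat("<pdb_structure> ", x$source_id, "\n",
      "  protein atoms: ", nrow(x$atoms),
      " (chains ", paste(sort(unique(x$atoms$chain)), collapse = ","), ")\n",
      "  hetero atoms:  ", nrow(x$het), "\n", sep = "")
  invisible(x)
}
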