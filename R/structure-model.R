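# Structure model: a flat atom table behind a light S3 class.  Author
# residue numbering is preserved verbatim; hydrogens are dropped on read and
# all downstream geometry uses heavy atoms only.

ATOM_COLUMNS <- c("chain", "resno", "insert", "resid", "elety", "elesy",
                  "x", "y", "z", "o", "b", "alt", "het")

#' Construct a protein structure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety` (atom name), `elesy` (element symbol), `x`, `y`, `z` (Angstrom),
#'   `o` (occupancy), `b` (B-factor), `alt` (altloc, "" if none) and `het`
#'   (logical, TRUE for ligand/heteroatom residues).  Missing bookkeeping
#'   columns are filled with defaults.
#' @param id free-form label.
#' @return object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, id = "") {
  stopifnot(is.data.frame(atoms))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$elesy)) atoms$elesy <- guess_element(atoms$elety)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  missing_cols <- setdiff(ATOM_COLUMNS, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, ATOM_COLUMNS]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  if (any(!nzchar(atoms$elesy))) stop("empty element symbol")
  structure(list(id = id, atoms = atoms), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("protein_structure '%s': %d atoms, %d residues, chains [%s]%s\n",
              x$id, nrow(a),
              nrow(unique(a[, c("chain", "resno", "insert")])),
              paste(unique(a$chain), collapse = ","),
              if (any(a$het)) sprintf(", %d hetero atoms", sum(a$het)) else ""))
  invisible(x)
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", trimws(elety))
  one <- toupper(substr(e, 1, 1))
  ifelse(one %in% c("C", "N", "O", "S", "P", "H"), one, toupper(substr(e, 1, 2)))
}

atom_xyz <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

set_atom_xyz <- function(s, xyz) {
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Chain identifiers of a structure
#' @param s a `protein_structure`.
#' @return character vector of chain ids in order of appearance.
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

WATER_RESIDS <- c("HOH", "WAT", "DOD")

#' Read a PDB-format coordinate file
#'
#' Parses ATOM/HETATM records of the first MODEL into a [protein_structure].
#' Hydrogen/deuterium atoms are dropped; only blank or 'A' altlocs are kept;
#' HETATM residues are flagged hetero.  Parsing of the fixed-width records is
#' delegated to \pkg{bio3d} after a validation pass that reports malformed
#' records with their line numbers.
#'
#' @param input path to a PDB file, or a character vector/string of PDB text.
#' @param keep_altlocs altloc codes retained (default blank and "A").
#' @param id label for the structure; defaults to the file name.
#' @return a [protein_structure].
#' @export
read_pdb <- function(input, keep_altlocs = c("", "A"), id = NULL) {
  is_text <- length(input) > 1 || grepl("\n", input[1]) ||
    grepl("^(ATOM|HETATM|HEADER|REMARK|MODEL|CRYST1|TITLE|END)", input[1])
  if (is_text) {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
    if (is.null(id)) id <- "pdb_text"
  } else {
    path <- input
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  }
  if (length(lines) == 0 || !any(nzchar(trimws(lines))))
    stop("empty PDB input")
  validate_pdb_lines(lines)
  if (!any(grepl("^(ATOM  |HETATM)", lines)))
    stop("no ATOM/HETATM records in PDB input")
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  a$alt[is.na(a$alt)] <- ""
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- " "
  keep <- a$alt %in% keep_altlocs & !(a$elesy %in% c("H", "D"))
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no heavy atoms left after altloc/hydrogen filtering")
  elesy <- ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                  guess_element(a$elety), trimws(a$elesy))
  atoms <- data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
                      resid = a$resid, elety = a$elety, elesy = elesy,
                      x = a$x, y = a$y, z = a$z,
                      o = ifelse(is.na(a$o), 1, pmin(1, pmax(0, a$o))),
                      b = ifelse(is.na(a$b), 0, a$b),
                      alt = a$alt, het = a$type == "HETATM",
                      stringsAsFactors = FALSE)
  protein_structure(atoms, id = id)
}

validate_pdb_lines <- function(lines) {
  idx <- grep("^(ATOM  |HETATM)", lines)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed PDB record at line %d: fewer than 54 columns", i))
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v))
        stop(sprintf("malformed PDB record at line %d: non-numeric coordinate field", i))
    }
  }
  invisible(TRUE)
}

#' Write a structure as a PDB-format file
#'
#' Emits fixed-width ATOM/HETATM records (3-decimal coordinates), TER records
#' between chains and a final END record.
#'
#' @param s a [protein_structure].
#' @param path output file path.
#' @return invisibly, the path written.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "protein_structure"))
  a <- s$atoms
  if (nrow(a) == 0) {
    writeLines("END", path)
    return(invisible(path))
  }
  if (any(nchar(trimws(a$elety)) > 4))
    stop("atom name longer than 4 characters: ",
         paste(unique(a$elety[nchar(trimws(a$elety)) > 4]), collapse = ", "))
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = ifelse(nzchar(a$insert), a$insert, NA),
                   alt = ifelse(nzchar(a$alt), a$alt, NA),
                   o = a$o, b = a$b, elesy = a$elesy,
                   chainter = TRUE, end = TRUE)
  invisible(path)
}

#' Define a named set of residue ranges
#'
#' @param name label, e.g. "lobe I".
#' @param ranges either a data.frame with columns `chain`, `start`, `end`
#'   (inclusive author numbering) or a compact string such as
#'   `"A:23-110,A:210-231"`.
#' @return object of class `domain_def`.
#' @export
domain_def <- function(name, ranges) {
  if (is.character(ranges)) ranges <- parse_domain_spec(ranges)
  stopifnot(is.data.frame(ranges), nrow(ranges) >= 1,
            all(c("chain", "start", "end") %in% names(ranges)))
  if (any(ranges$start > ranges$end)) stop("domain range with start > end")
  structure(list(name = name, ranges = ranges), class = "domain_def")
}

#' Parse a compact residue-range specification
#'
#' @param spec string like `"A:23-110,A:210-231"`; a bare `"23-110"` applies
#'   to every chain (chain recorded as `"*"`).
#' @return data.frame with columns `chain`, `start`, `end`.
#' @export
parse_domain_spec <- function(spec) {
  parts <- trimws(unlist(strsplit(spec, ",", fixed = TRUE)))
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop("empty domain specification")
  out <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(?:([A-Za-z0-9]):)?(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
    if (!length(m)) stop("cannot parse domain range: '", p, "'")
    data.frame(chain = if (nzchar(m[2])) m[2] else "*",
               start = as.integer(m[3]), end = as.integer(m[4]))
  })
  do.call(rbind, out)
}

chain_agnostic <- function(dom) {
  if (is.null(dom)) return(NULL)
  if (is.character(dom)) dom <- domain_def("selection", dom)
  dom$ranges$chain <- "*"
  dom
}

domain_mask <- function(s, dom, chain_map = NULL) {
  a <- s$atoms
  if (is.null(dom)) return(rep(TRUE, nrow(a)))
  r <- dom$ranges
  if (!is.null(chain_map)) {
    known <- r$chain %in% names(chain_map)
    r$chain[known] <- unname(chain_map[r$chain[known]])
  }
  keep <- rep(FALSE, nrow(a))
  for (k in seq_len(nrow(r))) {
    hit <- a$resno >= r$start[k] & a$resno <= r$end[k]
    if (r$chain[k] != "*") hit <- hit & a$chain == r$chain[k]
    keep <- keep | hit
  }
  keep
}

#' Select atoms by domain and atom name
#'
#' Returns coordinates in residue order, skipping (and reporting) residues
#' that lack a requested atom.
#'
#' @param s a [protein_structure].
#' @param domain a [domain_def], a compact range string, or NULL for all
#'   residues.
#' @param atom_names atom names to extract per residue (default `"CA"`).
#' @param include_het include hetero residues (default FALSE).
#' @return list with `xyz` (n x 3 matrix), `index` (data.frame chain, resno,
#'   insert, resid, elety per row of `xyz`) and `missing` (data.frame of
#'   residues skipped for lacking a requested atom).
#' @export
select_atoms <- function(s, domain = NULL, atom_names = "CA",
                         include_het = FALSE) {
  stopifnot(inherits(s, "protein_structure"))
  if (is.character(domain)) domain <- domain_def("selection", domain)
  a <- s$atoms
  keep <- domain_mask(s, domain)
  if (!include_het) keep <- keep & !a$het
  keep <- keep & trimws(a$elety) %in% atom_names
  sel <- a[keep, , drop = FALSE]
  if (nrow(sel) == 0) stop("selection resolves to zero atoms")
  key <- paste(sel$chain, sel$resno, sel$insert)
  n_per <- table(key)[unique(key)]
  complete <- names(n_per)[n_per == length(atom_names)]
  missing_res <- unique(sel[!(key %in% complete),
                            c("chain", "resno", "insert", "resid")])
  sel <- sel[key %in% complete, , drop = FALSE]
  if (nrow(sel) == 0) stop("selection resolves to zero complete residues")
  ord <- order(sel$chain, sel$resno, sel$insert,
               match(trimws(sel$elety), atom_names))
  sel <- sel[ord, , drop = FALSE]
  list(xyz = as.matrix(sel[, c("x", "y", "z")]),
       index = sel[, c("chain", "resno", "insert", "resid", "elety")],
       missing = missing_res)
}

#' Extract one chain as a structure
#' @param s a [protein_structure].
#' @param chain chain identifier.
#' @param include_het keep hetero residues of that chain.
#' @return a [protein_structure] restricted to `chain`.
#' @export
get_chain <- function(s, chain, include_het = TRUE) {
  a <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  if (!include_het) a <- a[!a$het, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms in chain ", chain)
  protein_structure(a, id = paste0(s$id, ":", chain))
}

#' Drop water molecules from a structure
#' @param s a [protein_structure].
#' @return structure without HOH/WAT/DOD residues.
#' @export
remove_waters <- function(s) {
  a <- s$atoms[!(s$atoms$resid %in% WATER_RESIDS), , drop = FALSE]
  protein_structure(a, id = s$id)
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' One-letter sequence of a chain
#'
#' @param s a [protein_structure].
#' @param chain chain id; default first chain.
#' @return list with `one_letter` string (unknown residues as "X") and
#'   `first_number`, the author number of the first residue.
#' @export
structure_sequence <- function(s, chain = chain_ids(s)[1]) {
  a <- s$atoms[s$atoms$chain == chain & !s$atoms$het, , drop = FALSE]
  if (nrow(a) == 0) stop("no protein residues in chain ", chain)
  res <- unique(a[, c("resno", "insert", "resid")])
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  letters1 <- AA3TO1[res$resid]
  letters1[is.na(letters1)] <- "X"
  list(one_letter = paste(letters1, collapse = ""),
       first_number = res$resno[1])
}
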