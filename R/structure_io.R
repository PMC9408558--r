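#' @useDynLib abcconftor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim runif rnorm setNames
#' @importFrom utils read.table write.table head tail
NULL

## Structures are held as a plain atom table (one row per atom) plus entry
## metadata, mirroring the layout practitioners know from bio3d's pdb$atom.
## Author residue numbering is canonical; label_seq (1-based polymer index
## per chain) is derived from residue order and kept as an auxiliary column
## for mapping sequence-coordinate domain hits onto the structure.

#' Construct a structure object from an atom table
#'
#' @param atom data.frame with columns `chain`, `resno`, `ins`, `resname`,
#'   `atom`, `x`, `y`, `z` and optionally `het` (logical; HETATM records)
#'   and `label_seq` (1-based polymer sequence position per chain, the
#'   mmCIF `label_seq_id`; derived from residue order when absent).
#' @param entry_id entry identifier (PDB ID or model identifier).
#' @param source `"experimental"` or `"predicted"`.
#' @param assembly_id optional assembly identifier.
#' @return An object of class `abc_structure`.
#' @export
abc_structure <- function(atom, entry_id = "unknown",
                          source = c("experimental", "predicted"),
                          assembly_id = NULL) {
  source <- match.arg(source)
  stopifnot(is.data.frame(atom))
  needed <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atom))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(atom$ins)) atom$ins <- NA_character_
  if (is.null(atom$het)) atom$het <- FALSE
  if (any(!is.finite(atom$x) | !is.finite(atom$y) | !is.finite(atom$z)))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atom$resname)))
    stop("empty residue names")
  prot <- atom[!atom$het, , drop = FALSE]
  if (nrow(prot) == 0L)
    stop("empty-structure error: no protein (ATOM) residues in '", entry_id, "'")
  atom <- .order_atoms(atom)
  ## label_seq: 1-based polymer (sequence) position per chain. When the
  ## input provides it (mmCIF label_seq_id semantics) it is kept, so
  ## unresolved residues leave visible gaps; otherwise it is derived from
  ## residue order.
  if (is.null(atom$label_seq) || all(is.na(atom$label_seq[!atom$het])))
    atom$label_seq <- .label_seq(atom)
  x <- list(entry_id = entry_id, assembly_id = assembly_id,
            source = source, atom = atom)
  class(x) <- "abc_structure"
  x
}

## insertion codes sort after the uninserted residue, alphabetically
.ins_rank <- function(ins) {
  r <- match(ins, c(NA, LETTERS, letters))
  r[is.na(r)] <- 1L
  r
}

.order_atoms <- function(atom) {
  chain_rank <- match(atom$chain, unique(atom$chain))
  o <- order(atom$het, chain_rank, atom$resno, .ins_rank(atom$ins))
  atom <- atom[o, , drop = FALSE]
  rownames(atom) <- NULL
  atom
}

## 1-based polymer position per chain, over protein residues only
.label_seq <- function(atom) {
  key <- paste(atom$chain, atom$resno, ifelse(is.na(atom$ins), "", atom$ins))
  out <- rep(NA_integer_, nrow(atom))
  for (ch in unique(atom$chain[!atom$het])) {
    sel <- !atom$het & atom$chain == ch
    out[sel] <- match(key[sel], unique(key[sel]))
  }
  out
}

#' @export
print.abc_structure <- function(x, ...) {
  prot <- x$atom[!x$atom$het, ]
  nres <- length(unique(paste(prot$chain, prot$resno, prot$ins)))
  cat("abc_structure '", x$entry_id, "' (", x$source, ")\n", sep = "")
  cat("  chains: ", paste(chain_ids(x), collapse = " "),
      " | residues: ", nres,
      " | atoms: ", nrow(prot),
      " | hetatm: ", sum(x$atom$het), "\n", sep = "")
  invisible(x)
}

#' Chain identifiers of a structure (protein chains, in file order)
#' @param structure an `abc_structure`
#' @export
chain_ids <- function(structure) {
  unique(structure$atom$chain[!structure$atom$het])
}

#' Read a macromolecular structure from PDB or PDBx/mmCIF
#'
#' Reads the first model only. All chains of the deposited assembly are
#' retained; HETATM-only content is excluded from residue iteration but kept
#' in the atom table (flagged `het`). Alternate locations are reduced to the
#' highest-occupancy conformer (ties broken by altloc letter).
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.cif`/`.mmcif` vs anything else),
#'   `"pdb"` or `"mmcif"`.
#' @param entry_id entry identifier; defaults to the file base name.
#' @param source `"experimental"` or `"predicted"`.
#' @return An `abc_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           entry_id = NULL,
                           source = c("experimental", "predicted")) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (is.null(entry_id))
    entry_id <- sub("\\.(pdb[0-9]*|ent|cif|mmcif)$", "",
                    basename(path), ignore.case = TRUE)
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE,
                                         rm.alt = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("parse error in '", path, "' (", format, "): ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("empty-structure error: no atoms parsed from '", path, "'")
  at <- .drop_altlocs(at)
  atom <- data.frame(chain = as.character(at$chain),
                     resno = as.integer(at$resno),
                     ins = as.character(at$insert),
                     resname = as.character(at$resid),
                     atom = as.character(at$elety),
                     x = at$x, y = at$y, z = at$z,
                     het = at$type == "HETATM",
                     stringsAsFactors = FALSE)
  atom$chain[is.na(atom$chain)] <- " "
  abc_structure(atom, entry_id = entry_id, source = source)
}

## keep highest-occupancy altloc per (chain, resno, ins, atom name); ties by
## altloc letter order
.drop_altlocs <- function(at) {
  alt <- at$alt
  if (is.null(alt) || all(is.na(alt) | alt %in% c("", "A", ".")))
    return(at)
  occ <- at$o
  if (is.null(occ)) occ <- rep(1, nrow(at))
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  alt_chr <- ifelse(is.na(alt) | alt == ".", "", alt)
  o <- order(key, -occ, alt_chr)
  at <- at[o, , drop = FALSE]
  at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
     drop = FALSE]
}

#' Extract the C-alpha trace of a structure
#'
#' Returns one point per protein residue possessing a CA atom, in chain
#' order then residue order; residues lacking a CA are skipped and counted.
#'
#' @param structure an `abc_structure`.
#' @param chains optional character vector of chain ids to keep.
#' @param resno_range optional `c(lo, hi)` author-residue-number filter
#'   (applied after the chain filter).
#' @return An `abc_coordset`: list with `labels` (data.frame `chain`,
#'   `resno`, `ins`, `label_seq`), `xyz` (N x 3 matrix, Angstrom) and
#'   `n_skipped` (residues without CA).
#' @export
extract_ca <- function(structure, chains = NULL, resno_range = NULL) {
  stopifnot(inherits(structure, "abc_structure"))
  at <- structure$atom[!structure$atom$het, , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (!is.null(resno_range)) {
    stopifnot(length(resno_range) == 2L)
    at <- at[at$resno >= resno_range[1] & at$resno <= resno_range[2], ,
             drop = FALSE]
  }
  if (nrow(at) == 0L)
    stop("empty-selection error: no residues match the selection")
  key <- paste(at$chain, at$resno, ifelse(is.na(at$ins), "", at$ins))
  n_res <- length(unique(key))
  ca <- at[at$atom == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$ins)), , drop = FALSE]
  coordset(labels = data.frame(chain = ca$chain, resno = ca$resno,
                               ins = ca$ins, label_seq = ca$label_seq,
                               stringsAsFactors = FALSE),
           xyz = cbind(x = ca$x, y = ca$y, z = ca$z),
           n_skipped = n_res - nrow(ca))
}

#' Construct a labelled coordinate set
#'
#' @param labels data.frame of residue identifiers (`chain`, `resno`,
#'   optional `ins`); must be unique.
#' @param xyz N x 3 numeric matrix (Angstrom).
#' @param n_skipped count of residues dropped on the way in.
#' @export
coordset <- function(labels, xyz, n_skipped = 0L) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(labels) == nrow(xyz))
  if (is.null(labels$ins)) labels$ins <- NA_character_
  key <- paste(labels$chain, labels$resno, ifelse(is.na(labels$ins), "", labels$ins))
  if (anyDuplicated(key)) stop("duplicate residue labels in coordinate set")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(labels = labels, xyz = xyz, n_skipped = as.integer(n_skipped)),
            class = "abc_coordset")
}

#' @export
print.abc_coordset <- function(x, ...) {
  cat("abc_coordset: ", nrow(x$xyz), " residues (",
      x$n_skipped, " skipped)\n", sep = "")
  invisible(x)
}

#' @export
length.abc_coordset <- function(x) nrow(x$xyz)

#' Write a structure as PDBx/mmCIF
#'
#' Emits a minimal `atom_site` category (author and label fields, model 1)
#' that round-trips through [read_structure()]. Multi-character chain ids
#' are preserved.
#'
#' @param structure an `abc_structure`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_mmcif <- function(structure, path) {
  stopifnot(inherits(structure, "abc_structure"))
  at <- structure$atom
  if (nrow(at[!at$het, , drop = FALSE]) == 0L)
    stop("refusing to write empty structure")
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  hdr <- c(paste0("data_", gsub("[^A-Za-z0-9_-]", "_", structure$entry_id)),
           "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  writeLines(hdr, con)
  elem <- substr(trimws(at$atom), 1L, 1L)
  lines <- sprintf(
    "%-6s %d %s %s . %s %s 1 %s %s %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
    ifelse(at$het, "HETATM", "ATOM"), seq_len(nrow(at)), elem, at$atom,
    at$resname, at$chain,
    ifelse(is.na(at$label_seq), ".", as.character(at$label_seq)),
    ifelse(is.na(at$ins) | at$ins == "", "?", at$ins),
    at$x, at$y, at$z, at$resno, at$resname, at$chain, at$atom)
  writeLines(lines, con)
  writeLines("#", con)
  invisible(path)
}

#' Apply a rigid-body transform to a structure
#'
#' Every atom position `x` is replaced by `R x + t`; labels are unchanged.
#'
#' @param structure an `abc_structure`.
#' @param rotation 3 x 3 proper orthonormal matrix (checked to 1e-6).
#' @param translation length-3 numeric vector.
#' @export
apply_transform <- function(structure, rotation, translation = c(0, 0, 0)) {
  stopifnot(inherits(structure, "abc_structure"))
  .check_rotation(rotation)
  stopifnot(length(translation) == 3L)
  xyz <- as.matrix(structure$atom[, c("x", "y", "z")])
  new_xyz <- xyz %*% t(rotation) +
    matrix(translation, nrow(xyz), 3, byrow = TRUE)
  structure$atom$x <- new_xyz[, 1]
  structure$atom$y <- new_xyz[, 2]
  structure$atom$z <- new_xyz[, 3]
  structure
}

.check_rotation <- function(rotation, tol = 1e-6) {
  if (!is.matrix(rotation) || any(dim(rotation) != c(3L, 3L)))
    stop("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > tol)
    stop("validation error: rotation is not orthonormal (tolerance 1e-6)")
  if (abs(det(rotation) - 1) > tol)
    stop("validation error: rotation determinant is not +1 (improper rotation)")
  invisible(TRUE)
}
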