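# V2000 old-style charge codes <-> formal charge (e)
.chgFromCode <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)
.codeFromChg <- function(q) {
  vapply(q, function(v) switch(as.character(v),
    `3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L, `-3` = 7L, 0L),
    integer(1))
}

.sdfToMolecule3D <- function(sdf, id, needsEmbedding = FALSE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  chgcode <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else
    rep(0L, nrow(ab))
  chgcode[is.na(chgcode)] <- 0L
  charge <- unname(.chgFromCode[as.character(chgcode)])
  charge[is.na(charge)] <- 0L
  atoms <- data.frame(element = element, charge = charge,
                      x = ab[, 1], y = ab[, 2], z = ab[, 3])
  bonds <- if (nrow(bb)) {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else NULL
  Molecule3D(id = id, atoms = atoms, bonds = bonds,
             needsEmbedding = needsEmbedding)
}

.smilesRecordToMolecule3D <- function(smiles, id) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineOB is required to parse SMILES input", call. = FALSE)
  txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"),
    options = data.frame(names = "h", args = ""))
  if (!nzchar(txt)) stop("SMILES could not be parsed: ", smiles, call. = FALSE)
  sset <- suppressWarnings(
    ChemmineR::read.SDFset(ChemmineR::read.SDFstr(strsplit(txt, "\n")[[1]])))
  if (length(sset) != 1L)
    stop("SMILES could not be parsed: ", smiles, call. = FALSE)
  mol <- .sdfToMolecule3D(sset[[1]], id, needsEmbedding = TRUE)
  if (nAtoms(mol) < 1L)
    stop("SMILES produced an empty molecule: ", smiles, call. = FALSE)
  mol
}

#' Read molecular structures from SMILES or SDF input
#'
#' Parses either a SMILES file (one record per line, an optional
#' whitespace-separated identifier after the SMILES string) or an SDF/MOL
#' V2000 file into a list of [Molecule3D-class] objects. SMILES parsing and
#' hydrogen completion are delegated to OpenBabel (via ChemmineOB);
#' molecules read from SMILES carry placeholder coordinates and are flagged
#' as needing [embed3d()]. SDF coordinates are preserved as printed.
#'
#' @param input path to a file, or a character vector of lines
#'   (`text = TRUE`).
#' @param format `"auto"` (default, decided by content), `"smiles"`, or
#'   `"sdf"`.
#' @param text logical; when `TRUE`, `input` is the content itself.
#' @param strict logical; when `TRUE` an unparsable record aborts the whole
#'   read. Default collects per-record errors as warnings and returns the
#'   parsable records.
#' @return list of [Molecule3D-class]; records without an identifier get
#'   stable sequential ids `mol_0001`, `mol_0002`, ...
#' @examples
#' mols <- readStructures("CCO ethanol", format = "smiles", text = TRUE)
#' nAtoms(mols[[1]])  # 9 with explicit hydrogens
#' @export
readStructures <- function(input, format = c("auto", "smiles", "sdf"),
                           text = FALSE, strict = FALSE) {
  format <- match.arg(format)
  lines <- if (text) {
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    if (!file.exists(input)) stop("file not found: ", input, call. = FALSE)
    readLines(input, warn = FALSE)
  }
  if (format == "auto") {
    format <- if (any(grepl("V2000", lines, fixed = TRUE)) ||
                  any(lines == "$$$$")) "sdf" else "smiles"
  }
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    warning("empty structure input; returning an empty list", call. = FALSE)
    return(list())
  }
  if (format == "sdf") {
    sset <- suppressWarnings(
      ChemmineR::read.SDFset(ChemmineR::read.SDFstr(lines)))
    valid <- ChemmineR::validSDF(sset)
    if (!all(valid)) {
      msg <- paste("invalid SDF record(s):",
                   paste(which(!valid), collapse = ", "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      sset <- sset[valid]
    }
    ids <- ChemmineR::sdfid(sset)
    ids[!nzchar(trimws(ids))] <- NA_character_
    out <- vector("list", length(sset))
    for (k in seq_along(sset)) {
      id <- if (is.na(ids[k])) sprintf("mol_%04d", k) else trimws(ids[k])
      out[[k]] <- .sdfToMolecule3D(sset[[k]], id)
    }
    return(out)
  }
  recs <- trimws(lines)
  recs <- recs[nzchar(recs) & !startsWith(recs, "#")]
  out <- list()
  errs <- character()
  for (k in seq_along(recs)) {
    tok <- strsplit(recs[k], "[[:space:]]+")[[1]]
    id <- if (length(tok) >= 2L) paste(tok[-1L], collapse = " ") else
      sprintf("mol_%04d", k)
    mol <- tryCatch(.smilesRecordToMolecule3D(tok[1L], id),
                    error = function(e) conditionMessage(e))
    if (is.character(mol)) {
      msg <- sprintf("record %d: %s", k, mol)
      if (strict) stop(msg, call. = FALSE)
      errs <- c(errs, msg)
    } else {
      out[[length(out) + 1L]] <- mol
    }
  }
  if (length(errs))
    warning("skipped unparsable SMILES record(s):\n",
            paste(errs, collapse = "\n"), call. = FALSE)
  out
}

.molecule3DToSDF <- function(mol) {
  n <- nAtoms(mol)
  ab <- matrix(0, nrow = n, ncol = 15,
               dimnames = list(paste(atomElements(mol), seq_len(n), sep = "_"),
                               c("C1", "C2", "C3", "C5", "C6", "C7", "C8",
                                 "C9", "C10", "C11", "C12", "C13", "C14",
                                 "C15", "C16")))
  ab[, 1:3] <- atomCoords(mol)
  ab[, "C6"] <- .codeFromChg(mol@atoms$charge)
  b <- molBonds(mol)
  bb <- matrix(0L, nrow = nrow(b), ncol = 7,
               dimnames = list(NULL, paste0("C", 1:7)))
  if (nrow(b)) {
    bb[, 1] <- b$i; bb[, 2] <- b$j; bb[, 3] <- b$order
  }
  header <- c(Molecule_Name = molId(mol), Source = "flavoqsar",
              Comment = "",
              Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                    n, nrow(b)))
  new("SDF", header = header, atomblock = ab, bondblock = bb,
      datablock = character(0))
}

#' Write Molecule3D objects to an SDF file
#'
#' @param mols a [Molecule3D-class] or a list of them.
#' @param path output file path.
#' @return invisibly, the path.
#' @seealso [readStructures()]
#' @export
writeStructuresSDF <- function(mols, path) {
  if (is(mols, "Molecule3D")) mols <- list(mols)
  sdfs <- lapply(mols, .molecule3DToSDF)
  sset <- new("SDFset", SDF = sdfs, ID = vapply(mols, molId, ""))
  ChemmineR::write.SDF(sset, file = path)
  invisible(path)
}
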