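#' Parse a PDB or mmCIF structure into a ProteinRecord
#'
#' Reads one polymer chain from a coordinate file, excluding hetero-atoms
#' and waters, and returns a normalized \code{\linkS4class{ProteinRecord}}
#' whose author (deposited) residue numbers are kept verbatim so that every
#' downstream coordinate can be reported in PDB residue space. Crystal
#' structures whose chains start above residue 1 (e.g. after an excluded
#' hetero-group at position 1) are therefore handled without any renumbering.
#'
#' Residues that lack a C-alpha atom stay in the sequence with an NA
#' coordinate row. Selenomethionine (MSE), although deposited as a
#' hetero-atom, is retained and mapped to M; other non-standard residues are
#' skipped with a warning.
#'
#' @param path path to the structure file.
#' @param format "pdb" or "mmcif"; guessed from the file extension by
#'   default.
#' @param chain chain identifier; default is the first polymer chain in the
#'   file.
#' @param group subgroup label to attach to the record.
#' @param id record identifier; defaults to the file base name.
#' @return A \code{\linkS4class{ProteinRecord}}.
#' @examples
#' fam <- generateFamily(familySpec(nProteins = 2, length = 60, seed = 1))
#' d <- tempfile(); dir.create(d)
#' emitFixtureFiles(fam$records, fam$truth, d)
#' parseStructure(file.path(d, paste0(recordId(fam$records[[1]]), ".pdb")))
#' @export
parseStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                           chain = NULL, group = "all", id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  at <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)$atom
    else .readCifAtoms(path),
    error = function(e) stop("could not parse structure file '", path,
                             "': ", conditionMessage(e)))
  # altloc: keep blank or 'A'
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  polymer <- at$type == "ATOM" & at$resid != "HOH"
  mse <- at$type == "HETATM" & at$resid == "MSE"
  at <- at[polymer | mse, , drop = FALSE]
  if (nrow(at) == 0L) stop("no standard residues in '", path, "'")
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no residues in chain '", chain, "' of ", path)

  key <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  first <- !duplicated(key)
  resno <- at$resno[first]
  resid3 <- at$resid[first]
  keyu <- key[first]
  aa1 <- suppressWarnings(bio3d::aa321(resid3))
  known <- aa1 %in% AA20
  if (any(!known)) {
    warning("skipping ", sum(!known), " residue(s) with unknown code(s): ",
            paste(unique(resid3[!known]), collapse = ", "))
  }
  resno <- resno[known]; aa1 <- aa1[known]; keyu <- keyu[known]
  if (length(resno) == 0L) stop("no standard residues in chain '", chain, "'")
  # insertion-coded duplicates of an author number cannot be represented in
  # a strictly increasing integer numbering; keep the first occurrence
  keep <- c(TRUE, diff(resno) > 0L)
  if (!all(keep)) {
    warning("dropping ", sum(!keep),
            " residue(s) with non-increasing author numbers (insertion codes)")
    resno <- resno[keep]; aa1 <- aa1[keep]; keyu <- keyu[keep]
  }
  coords <- matrix(NA_real_, nrow = length(resno), ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  ca <- at[at$elety == "CA", , drop = FALSE]
  cakey <- paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
  hit <- match(keyu, cakey)
  has <- !is.na(hit)
  coords[has, ] <- as.matrix(ca[hit[has], c("x", "y", "z")])

  if (is.null(id)) id <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                             ignore.case = TRUE)
  ProteinRecord(id = id, sequence = paste(aa1, collapse = ""),
                residueNumbers = resno, caCoords = coords,
                group = group, source = format)
}

# mmCIF _atom_site reader. The loop_ header is self-describing, so field
# positions are taken from the tag list rather than assumed; this stays
# correct for any writer's column order. Returns a table with the same
# columns parseStructure() consumes from bio3d's PDB parser.
.readCifAtoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tagIdx <- grep("^_atom_site\\.", lines)
  if (!length(tagIdx)) stop("no _atom_site loop found")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tagIdx]))
  body <- lines[seq.int(max(tagIdx) + 1L, length(lines))]
  stopRow <- grep("^\\s*(#|loop_|_|data_)", body)
  if (length(stopRow)) body <- body[seq_len(stopRow[1L] - 1L)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty _atom_site loop")
  fields <- strsplit(trimws(body), "\\s+")
  n <- vapply(fields, length, integer(1))
  fields <- fields[n == length(tags)]
  if (!length(fields)) stop("malformed _atom_site rows")
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  get <- function(nm, alt = NULL) {
    if (nm %in% tags) m[, nm]
    else if (!is.null(alt) && alt %in% tags) m[, alt]
    else rep(NA_character_, nrow(m))
  }
  blank <- function(v) ifelse(v %in% c(".", "?"), NA_character_, v)
  out <- data.frame(
    type = get("group_PDB"),
    elety = gsub("\"", "", get("label_atom_id", "auth_atom_id")),
    alt = blank(get("label_alt_id")),
    resid = get("label_comp_id", "auth_comp_id"),
    chain = get("auth_asym_id", "label_asym_id"),
    resno = as.integer(blank(get("auth_seq_id", "label_seq_id"))),
    insert = blank(get("pdbx_PDB_ins_code")),
    x = as.numeric(get("Cartn_x")), y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")), stringsAsFactors = FALSE)
  model <- suppressWarnings(as.integer(blank(get("pdbx_PDB_model_num"))))
  if (!all(is.na(model))) out <- out[model == model[!is.na(model)][1L], ]
  out
}

# DSSP 8-state -> 3-state reduction: H,G,I -> H; E,B -> E; rest -> C
.ss8to3 <- function(ss8) {
  out <- rep("C", length(ss8))
  out[ss8 %in% c("H", "G", "I")] <- "H"
  out[ss8 %in% c("E", "B")] <- "E"
  out
}

#' Attach secondary structure from a DSSP output file
#'
#' Parses classic DSSP text output (v2/v3 column layout), reduces the
#' 8-state assignment to 3 states (H,G,I to H; E,B to E; everything else,
#' including turns, bends and blanks, to C) and aligns it to a record by
#' author residue number. Residues of the record not covered by the DSSP
#' file are assigned coil ("C").
#'
#' @param path DSSP output file.
#' @param record the \code{\linkS4class{ProteinRecord}} to annotate.
#' @param chain restrict to one chain id; default uses all rows.
#' @return The record with \code{ss3} populated.
#' @export
parseDssp <- function(path, record, chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) stop("not a DSSP output file: ", path)
  body <- lines[seq.int(hdr[1L] + 1L, length(lines))]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14L, 14L)
  body <- body[aa != "!"]                      # chain breaks
  if (length(body) == 0L) stop("DSSP file has no residue rows: ", path)
  resno <- suppressWarnings(as.integer(substr(body, 6L, 10L)))
  ch <- substr(body, 12L, 12L)
  ss8 <- substr(body, 17L, 17L)
  ok <- !is.na(resno)
  if (!is.null(chain)) ok <- ok & ch == chain
  resno <- resno[ok]; ss8 <- ss8[ok]
  ss3v <- .ss8to3(ss8)
  pos <- match(residueNumbers(record), resno)
  if (all(is.na(pos)))
    stop("no DSSP residue numbers overlap record '", recordId(record), "'")
  out <- rep("C", seqLength(record))
  out[!is.na(pos)] <- ss3v[pos[!is.na(pos)]]
  ss3(record) <- paste(out, collapse = "")
  record
}

#' Read / write FASTA files as ProteinRecord lists
#'
#' \code{parseFasta} reads an amino-acid FASTA file into sequence-only
#' records (contiguous residue numbering from 1, no coordinates);
#' \code{writeFasta} writes records back out. Identifiers are the first
#' whitespace-delimited token of each header; sequences are uppercased.
#'
#' @param path FASTA file.
#' @param group subgroup label applied to all records.
#' @return \code{parseFasta}: list of \code{\linkS4class{ProteinRecord}};
#'   \code{writeFasta}: invisibly, the path.
#' @export
parseFasta <- function(path, group = "all") {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  lapply(seq_along(set), function(i) {
    ProteinRecord(id = ids[i], sequence = toupper(as.character(set[[i]])),
                  group = group, source = "fasta_only")
  })
}

#' @param records list of ProteinRecord (or a ProteinFamily).
#' @rdname parseFasta
#' @export
writeFasta <- function(records, path) {
  records <- .asRecordList(records)
  seqs <- Biostrings::AAStringSet(
    vapply(records, aaSequence, character(1)))
  names(seqs) <- vapply(records, recordId, character(1))
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}
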