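# Structure reading/writing, atom selection, trajectory containers.
# PDB and mmCIF parsing is delegated to bio3d; the structures are kept
# as a plain atom table ("structure3d") so downstream geometry never
# depends on reader internals.

#' Construct a structure from an atom table
#'
#' @param atom data frame with columns `chain`, `resno`, `resid`,
#'   `elety`, `x`, `y`, `z` and optionally `alt`, `occ`, `element`.
#' @param model_index which model of the source file this is (1-based).
#' @param numbering_offset integer added to file residue numbers to
#'   obtain mature-peptide numbering (signal peptide removed). All
#'   residue ranges passed to [select_atoms()] are interpreted in
#'   mature numbering.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atom, model_index = 1L, numbering_offset = 0L) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atom))
  if (length(miss))
    stop("atom table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z)))
    stop("non-finite atom coordinates", call. = FALSE)
  if (any(!nzchar(atom$elety)))
    stop("empty atom names", call. = FALSE)
  atom$chain <- as.character(atom$chain)
  atom$resno <- as.integer(atom$resno)
  atom$resid <- as.character(atom$resid)
  atom$elety <- as.character(atom$elety)
  if (is.null(atom$alt)) atom$alt <- ""
  if (is.null(atom$occ)) atom$occ <- 1
  if (is.null(atom$element)) atom$element <- guess_element(atom$elety)
  rownames(atom) <- NULL
  structure(list(atom = atom,
                 model_index = as.integer(model_index),
                 numbering_offset = as.integer(numbering_offset)),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", nrow(x$atom), "atoms,",
      length(unique(x$atom$chain)), "chain(s) [",
      paste(unique(x$atom$chain), collapse = " "), "], model",
      x$model_index, ", numbering offset", x$numbering_offset, "\n")
  invisible(x)
}

guess_element <- function(elety) {
  e <- sub("^[0-9']+", "", toupper(elety))
  two <- substr(e, 1L, 2L)
  one <- substr(e, 1L, 1L)
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "SE"),
         two, one)
}

#' Read a structure from PDB or mmCIF
#'
#' @param path file path.
#' @param format `"auto"` (by extension: .pdb/.ent vs .cif/.mmcif),
#'   `"pdb"` or `"mmcif"`.
#' @param model model number to extract (1-based) for multi-model files.
#' @param numbering_offset see [structure3d()].
#' @param keep_hydrogens hydrogens are dropped by default; all geometry
#'   in this package uses heavy atoms only.
#' @return a `structure3d`. Alternate locations are resolved by keeping
#'   the highest-occupancy conformer (ties broken by altloc label
#'   order).
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model = 1L, numbering_offset = 0L,
                           keep_hydrogens = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = , ent = , pdb1 = "pdb",
      cif = , mmcif = "mmcif",
      stop("cannot infer format from extension '.", ext, "'",
           call. = FALSE))
  }
  pdb <- if (format == "pdb") {
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                     rm.alt = FALSE, verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                     verbose = FALSE))
  }
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  model <- as.integer(model)
  if (model < 1L || model > n_models)
    stop("model ", model, " not found (file has ", n_models, " model",
         if (n_models > 1L) "s", ")", call. = FALSE)
  structure_from_bio3d(pdb, model = model,
                       numbering_offset = numbering_offset,
                       keep_hydrogens = keep_hydrogens)
}

structure_from_bio3d <- function(pdb, model = 1L, numbering_offset = 0L,
                                 keep_hydrogens = FALSE) {
  at <- pdb$atom
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
  atom <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    occ = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    element = if (!is.null(at$elesy) && !all(is.na(at$elesy)))
      ifelse(is.na(at$elesy) | !nzchar(at$elesy),
             guess_element(at$elety), toupper(trimws(at$elesy)))
      else guess_element(at$elety),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE)
  atom$chain[is.na(atom$chain)] <- " "
  if (!keep_hydrogens)
    atom <- atom[!(atom$element %in% c("H", "D")), , drop = FALSE]
  atom <- resolve_altloc(atom)
  structure3d(atom, model_index = model,
              numbering_offset = numbering_offset)
}

# Keep the highest-occupancy altloc per (chain, resno, elety); ties
# broken by altloc label order ('' sorts first, then A, B, ...).
resolve_altloc <- function(atom) {
  if (all(atom$alt == "")) return(atom)
  key <- paste(atom$chain, atom$resno, atom$elety, sep = "\r")
  ord <- order(key, -atom$occ, atom$alt)
  keep <- !duplicated(key[ord])
  atom <- atom[sort(ord[keep]), , drop = FALSE]
  rownames(atom) <- NULL
  atom
}

#' Write a structure to PDB or mmCIF
#'
#' PDB writing goes through [bio3d::write.pdb()]; mmCIF output is a
#' minimal `atom_site` loop sufficient for round-tripping atom tables.
#'
#' @param s a `structure3d`.
#' @param path output path.
#' @param format `"auto"`, `"pdb"` or `"mmcif"`.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "mmcif")) {
  stopifnot(inherits(s, "structure3d"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  at <- s$atom
  if (format == "pdb") {
    xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
    bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno,
                     resid = at$resid, chain = at$chain,
                     elety = at$elety, o = at$occ,
                     b = rep(0, nrow(at)), elesy = at$element)
  } else {
    write_mmcif(at, path)
  }
  invisible(path)
}

write_mmcif <- function(at, path) {
  lines <- c(
    "data_structure",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
            seq_len(nrow(at)), at$element, at$elety, at$resid, at$chain,
            at$resno, at$x, at$y, at$z, at$occ,
            at$resno, at$resid, at$chain, at$elety),
    "#")
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory as a list of structures
#'
#' Multi-model PDB files yield one `structure3d` per MODEL record;
#' plain whitespace XYZ frame series (n-atoms line, comment line, then
#' `name x y z` rows per frame) are also supported.
#'
#' @param path file path.
#' @param format `"auto"`, `"pdb"` or `"xyz"`.
#' @inheritParams load_structure
#' @return list of `structure3d`, one per frame, in file order.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz"),
                            numbering_offset = 0L,
                            keep_hydrogens = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "xyz") "xyz" else "pdb"
  }
  if (format == "pdb") {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                            verbose = FALSE))
    n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
    lapply(seq_len(n_models), function(m) {
      st <- structure_from_bio3d(pdb, model = m,
                                 numbering_offset = numbering_offset,
                                 keep_hydrogens = keep_hydrogens)
      st
    })
  } else {
    read_xyz_frames(path, numbering_offset = numbering_offset)
  }
}

# Minimal XYZ frame-series reader (no installed R package reads this
# trajectory dialect). Atom names become elety; residues are numbered
# sequentially and assigned to chain "A".
read_xyz_frames <- function(path, numbering_offset = 0L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) %in% integer(0)]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n))
      stop("malformed XYZ file at line ", i, ": expected atom count",
           call. = FALSE)
    if (i + 1L + n > length(lines))
      stop("truncated XYZ frame starting at line ", i, call. = FALSE)
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(parts) < 4L))
      stop("malformed XYZ atom row in frame starting at line ", i,
           call. = FALSE)
    nm <- vapply(parts, `[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    atom <- data.frame(chain = "A", resno = seq_len(n), resid = "UNK",
                       elety = nm, x = xyz[, 1L], y = xyz[, 2L],
                       z = xyz[, 3L], stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <-
      structure3d(atom, model_index = length(frames) + 1L,
                  numbering_offset = numbering_offset)
    i <- i + 2L + n
  }
  frames
}

#' Write a list of structures as a multi-model PDB
#'
#' @param frames list of `structure3d` sharing one atom layout.
#' @param path output path.
#' @export
write_trajectory <- function(frames, path) {
  stopifnot(length(frames) >= 1L)
  at <- frames[[1L]]$atom
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    a <- frames[[m]]$atom
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)),
      ifelse(nchar(a$elety) < 4L, paste0(" ", a$elety), a$elety),
      a$resid, a$chain, a$resno, a$x, a$y, a$z, a$occ %||% 1, 0,
      a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Labelled point set
#'
#' @param labels data frame (one row per point; typically chain,
#'   residue number in mature numbering, residue name) or character
#'   vector.
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param n_skipped residues skipped because they lacked the requested
#'   atom.
#' @return object of class `pointset` with fields `labels`, `xyz`,
#'   `n_skipped`.
#' @export
pointset <- function(labels, xyz, n_skipped = 0L) {
  xyz <- as_xyz_matrix(xyz)
  nlab <- if (is.data.frame(labels)) nrow(labels) else length(labels)
  if (nlab != nrow(xyz))
    stop("labels and points differ in length", call. = FALSE)
  if (nrow(xyz) < 1L) stop("empty point set", call. = FALSE)
  structure(list(labels = labels, xyz = xyz,
                 n_skipped = as.integer(n_skipped)),
            class = "pointset")
}

#' @export
print.pointset <- function(x, ...) {
  cat("pointset:", nrow(x$xyz), "points")
  if (x$n_skipped > 0L) cat(" (", x$n_skipped, " residues skipped)",
                            sep = "")
  cat("\n")
  invisible(x)
}

#' Select named atoms from residue ranges of one chain
#'
#' Residue ranges are given in mature-peptide numbering; the
#' structure's `numbering_offset` maps them onto file numbering.
#' Residues present in the range but lacking the named atom are skipped
#' and counted in the result's `n_skipped`.
#'
#' @param s a `structure3d`.
#' @param chain chain identifier.
#' @param residue_ranges list of inclusive `c(lo, hi)` integer pairs
#'   (mature numbering), or a 2-column matrix.
#' @param atom_name atom to pick per residue (default `"CA"`).
#' @return a `pointset`, points ordered by residue number.
#' @export
select_atoms <- function(s, chain, residue_ranges, atom_name = "CA") {
  stopifnot(inherits(s, "structure3d"))
  ranges <- normalize_ranges(residue_ranges)
  at <- s$atom
  mature <- at$resno + s$numbering_offset
  in_range <- rep(FALSE, nrow(at))
  for (k in seq_len(nrow(ranges)))
    in_range <- in_range | (mature >= ranges[k, 1L] &
                            mature <= ranges[k, 2L])
  sel_res <- at$chain == chain & in_range
  hit <- sel_res & at$elety == atom_name
  if (!any(hit)) {
    stop("empty selection: chain '", chain, "', atom '", atom_name,
         "' in the requested ranges", call. = FALSE)
  }
  res_all <- unique(at$resno[sel_res])
  res_hit <- unique(at$resno[hit])
  picked <- at[hit, , drop = FALSE]
  picked <- picked[order(picked$resno), , drop = FALSE]
  pointset(
    labels = data.frame(chain = picked$chain,
                        resno = picked$resno + s$numbering_offset,
                        resid = picked$resid, stringsAsFactors = FALSE),
    xyz = as.matrix(picked[, c("x", "y", "z")]),
    n_skipped = length(setdiff(res_all, res_hit)))
}

normalize_ranges <- function(residue_ranges) {
  if (is.matrix(residue_ranges)) {
    ranges <- residue_ranges
  } else if (is.list(residue_ranges)) {
    ranges <- do.call(rbind, residue_ranges)
  } else if (is.numeric(residue_ranges) && length(residue_ranges) == 2L) {
    ranges <- matrix(residue_ranges, ncol = 2L)
  } else stop("residue_ranges must be c(lo, hi) pairs", call. = FALSE)
  if (nrow(ranges) < 1L) stop("no residue ranges given", call. = FALSE)
  if (any(ranges[, 1L] > ranges[, 2L]))
    stop("range low > high", call. = FALSE)
  ranges
}

#' Write a point set as CSV
#'
#' @param ps a `pointset`.
#' @param path output path.
#' @export
write_pointset_csv <- function(ps, path) {
  stopifnot(inherits(ps, "pointset"))
  lab <- if (is.data.frame(ps$labels)) ps$labels
         else data.frame(label = ps$labels)
  df <- cbind(lab, x = ps$xyz[, 1L], y = ps$xyz[, 2L], z = ps$xyz[, 3L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
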