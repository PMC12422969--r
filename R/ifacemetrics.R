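# Interface geometry: centre-of-mass separations, marker-residue
# distances, and residue-residue contact footprints across an
# interface, plus set differences between footprints (e.g. wild type
# vs point mutant).

#' Residue selection specifier
#'
#' @param chain chain identifier.
#' @param residue_ranges inclusive `c(lo, hi)` pairs (mature
#'   numbering), as in [select_atoms()].
#' @return list of class `residue_selection`.
#' @export
residue_selection <- function(chain, residue_ranges) {
  structure(list(chain = chain, ranges = normalize_ranges(residue_ranges)),
            class = "residue_selection")
}

#' Centre-of-mass separation of two selections
#'
#' Euclidean distance between the unweighted centroids of two atom
#' selections (C-alpha by default), e.g. between the outer-chain NTD
#' tiers of two receptor structures.
#'
#' @param s a `structure3d`.
#' @param sel_a,sel_b [residue_selection()] objects or `pointset`s.
#' @param atom_name atom used when selections are residue ranges.
#' @return distance in Angstrom.
#' @export
com_separation <- function(s, sel_a, sel_b, atom_name = "CA") {
  a <- resolve_selection(s, sel_a, atom_name)
  b <- resolve_selection(s, sel_b, atom_name)
  vec_norm(colMeans(a$xyz) - colMeans(b$xyz))
}

resolve_selection <- function(s, sel, atom_name) {
  if (inherits(sel, "pointset")) return(sel)
  if (inherits(sel, "residue_selection"))
    return(select_atoms(s, sel$chain, sel$ranges, atom_name))
  stop("selection must be a residue_selection or pointset",
       call. = FALSE)
}

#' Distance between two residues under an atom rule
#'
#' @param s a `structure3d`.
#' @param res_a,res_b `c(chain, resno)` pairs (mature numbering).
#' @param atom_rule `"CA"` or `"CZ"` (that single atom) or
#'   `"closest-heavy"` (minimum over all heavy-atom pairs).
#' @return distance in Angstrom.
#' @export
residue_pair_distance <- function(s, res_a, res_b,
                                  atom_rule = c("CA", "CZ",
                                                "closest-heavy")) {
  atom_rule <- match.arg(atom_rule)
  xa <- residue_atoms(s, res_a, atom_rule)
  xb <- residue_atoms(s, res_b, atom_rule)
  min(cross_dist(xa, xb))
}

residue_atoms <- function(s, res, atom_rule) {
  chain <- as.character(res[[1L]])
  resno <- as.integer(res[[2L]]) - s$numbering_offset
  at <- s$atom
  rows <- at$chain == chain & at$resno == resno
  if (!any(rows))
    stop("residue ", res[[2L]], " of chain ", chain, " not found",
         call. = FALSE)
  if (atom_rule != "closest-heavy") {
    rows <- rows & at$elety == atom_rule
    if (!any(rows))
      stop("residue ", res[[2L]], " of chain ", chain, " has no '",
           atom_rule, "' atom", call. = FALSE)
  }
  as.matrix(at[rows, c("x", "y", "z"), drop = FALSE])
}

# All pairwise distances between rows of two coordinate matrices.
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Contact footprint between two selections
#'
#' All residue pairs (one residue from each selection) whose minimum
#' heavy-atom distance is at most `cutoff`, with that distance.
#'
#' @param s a `structure3d`.
#' @param sel_a,sel_b [residue_selection()] objects.
#' @param cutoff contact cutoff in Angstrom (default 4.0, minimum
#'   heavy-atom distance).
#' @return object of class `footprint`: a data frame `contacts` with
#'   columns `chain_a`, `resno_a`, `resid_a`, `chain_b`, `resno_b`,
#'   `resid_b`, `min_distance`, plus the `cutoff`.
#' @export
contact_footprint <- function(s, sel_a, sel_b, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  a <- selection_residue_table(s, sel_a)
  b <- selection_residue_table(s, sel_b)
  b_all <- do.call(rbind, b$coords)
  b_idx <- rep(seq_along(b$coords), vapply(b$coords, nrow, 0L))
  rows <- list()
  for (i in seq_along(a$coords)) {
    dmat <- cross_dist(a$coords[[i]], b_all)
    col_min <- apply(dmat, 2L, min)
    dmin <- tapply(col_min, b_idx, min)
    hit <- which(dmin <= cutoff)
    for (j in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain_a = a$info$chain[i], resno_a = a$info$resno[i],
        resid_a = a$info$resid[i],
        chain_b = b$info$chain[j], resno_b = b$info$resno[j],
        resid_b = b$info$resid[j],
        min_distance = unname(dmin[j]), stringsAsFactors = FALSE)
    }
  }
  contacts <- if (length(rows)) do.call(rbind, rows)
    else data.frame(chain_a = character(0), resno_a = integer(0),
                    resid_a = character(0), chain_b = character(0),
                    resno_b = integer(0), resid_b = character(0),
                    min_distance = numeric(0), stringsAsFactors = FALSE)
  rownames(contacts) <- NULL
  structure(list(contacts = contacts, cutoff = cutoff),
            class = "footprint")
}

# Split a selection into per-residue heavy-atom coordinate blocks.
selection_residue_table <- function(s, sel) {
  stopifnot(inherits(sel, "residue_selection"))
  at <- s$atom
  mature <- at$resno + s$numbering_offset
  keep <- at$chain == sel$chain & !(at$element %in% c("H", "D"))
  in_range <- rep(FALSE, nrow(at))
  for (k in seq_len(nrow(sel$ranges)))
    in_range <- in_range | (mature >= sel$ranges[k, 1L] &
                            mature <= sel$ranges[k, 2L])
  keep <- keep & in_range
  if (!any(keep))
    stop("empty selection: chain '", sel$chain, "'", call. = FALSE)
  at <- at[keep, , drop = FALSE]
  key <- paste(at$chain, at$resno)
  split_idx <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
  info <- data.frame(
    chain = vapply(split_idx, function(i) at$chain[i[1L]], ""),
    resno = vapply(split_idx, function(i)
      at$resno[i[1L]] + s$numbering_offset, 0L),
    resid = vapply(split_idx, function(i) at$resid[i[1L]], ""),
    stringsAsFactors = FALSE)
  coords <- lapply(split_idx, function(i)
    as.matrix(at[i, c("x", "y", "z"), drop = FALSE]))
  list(info = info, coords = coords)
}

#' @export
print.footprint <- function(x, ...) {
  cat("footprint:", nrow(x$contacts), "residue contacts at cutoff",
      x$cutoff, "A\n")
  invisible(x)
}

#' Contacts lost and gained between two footprints
#'
#' Set differences keyed on residue-pair identity (chains and residue
#' numbers), ignoring distances; e.g. contacts of a wild-type interface
#' absent from a mutant.
#'
#' @param a,b `footprint` objects with equal cutoffs.
#' @return list with data frames `lost` (contacts in `a` not in `b`)
#'   and `gained` (in `b` not in `a`).
#' @export
footprint_difference <- function(a, b) {
  stopifnot(inherits(a, "footprint"), inherits(b, "footprint"))
  if (!isTRUE(all.equal(a$cutoff, b$cutoff)))
    stop("footprints computed at different cutoffs (", a$cutoff,
         " vs ", b$cutoff, ") are not comparable", call. = FALSE)
  key <- function(f) paste(f$contacts$chain_a, f$contacts$resno_a,
                           f$contacts$chain_b, f$contacts$resno_b,
                           sep = "|")
  ka <- key(a)
  kb <- key(b)
  list(lost = a$contacts[!(ka %in% kb), , drop = FALSE],
       gained = b$contacts[!(kb %in% ka), , drop = FALSE])
}

#' Write footprint contacts as CSV
#'
#' @param fp a `footprint`.
#' @param path output path.
#' @export
write_footprint_csv <- function(fp, path) {
  utils::write.csv(fp$contacts, path, row.names = FALSE)
  invisible(path)
}
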