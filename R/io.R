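#' @title Trajectory and topology I/O
#' @description Multi-frame PDB (MODEL/ENDMDL), CHARMM-dialect DCD, XYZ and
#' TSV table readers/writers, plus the atom-selection mini-language used by
#' every analysis stage. Coordinates are Angstrom throughout; DCD stores
#' float32 and is promoted to float64 on read.
#' @name trajectory_io
NULL

pdb_chain_code <- function(chain) ifelse(chain == "SOLVENT", "W", chain)

#' Write a trajectory (or a topology's coordinates) as multi-frame PDB
#'
#' Minimal PDB: `CRYST1`, `MODEL`/`ATOM`/`ENDMDL` records; partial charges go
#' to the B-factor column; chain `SOLVENT` maps to PDB chain `W`.
#'
#' @param trajectory An [sf_trajectory()] (or `NULL` to write the topology's
#'   initial coordinates as a single model).
#' @param topology An [sf_topology] supplying atom metadata.
#' @param path Output file.
#' @export
write_pdb <- function(trajectory, topology, path) {
  if (is.null(trajectory))
    trajectory <- sf_trajectory(array(coords_of(topology),
                                      c(nrow(topology), 3, 1)),
                                box = attr(topology, "box"))
  con <- file(path, "w")
  on.exit(close(con))
  box <- trajectory$box[1, ]
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1], box[2], box[3], 90, 90, 90), con)
  ch <- pdb_chain_code(topology$chain)
  for (f in seq_len(n_frames(trajectory))) {
    writeLines(sprintf("MODEL %8d", f), con)
    X <- frame_coords(trajectory, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      topology$id %% 100000L, topology$name, topology$resname, ch,
      topology$resnum %% 10000L, X[, 1], X[, 2], X[, 3], 1.0,
      topology$charge), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

parse_pdb_frames <- function(lines) {
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0) {
    frames <- list(which(is_atom))
    if (length(frames[[1]]) == 0) frames <- list()
  } else {
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) < length(model_starts))
      abort(sprintf("truncated frame %d: MODEL without ENDMDL",
                    length(model_starts)))
    frames <- purrr::map2(model_starts, ends, function(s, e) {
      idx <- seq(s, e)
      idx[is_atom[idx]]
    })
  }
  frames
}

#' Read a trajectory file
#'
#' @param path File to read.
#' @param format `"PDB"`, `"DCD"` or `"XYZ"` (default: guessed from the
#'   extension).
#' @param topology Required for DCD (atom metadata lives outside the file);
#'   used for atom-count validation otherwise.
#' @return An [sf_trajectory()].
#' @export
read_trajectory <- function(path, format = NULL, topology = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  format <- toupper(format %||% tools::file_ext(path))
  switch(format,
    PDB = read_pdb_trajectory(path, topology),
    DCD = read_dcd_trajectory(path, topology),
    XYZ = read_xyz_trajectory(path, topology),
    abort(paste0("unsupported trajectory format: ", format)))
}

read_pdb_trajectory <- function(path, topology = NULL) {
  lines <- readLines(path)
  box <- c(0, 0, 0)
  cr <- which(startsWith(lines, "CRYST1"))
  if (length(cr))
    box <- as.numeric(c(substr(lines[cr[1]], 7, 15),
                        substr(lines[cr[1]], 16, 24),
                        substr(lines[cr[1]], 25, 33)))
  frames <- parse_pdb_frames(lines)
  if (length(frames) == 0)
    return(sf_trajectory(array(0, c(0, 3, 0)), times = numeric(0), box = box))
  na <- length(frames[[1]])
  for (f in seq_along(frames))
    if (length(frames[[f]]) != na)
      abort(sprintf("truncated frame %d: %d atoms, expected %d",
                    f, length(frames[[f]]), na))
  if (!is.null(topology) && na != nrow(topology))
    abort(sprintf("atom-count mismatch: file has %d, topology has %d",
                  na, nrow(topology)))
  coords <- array(NA_real_, c(na, 3, length(frames)))
  for (f in seq_along(frames)) {
    ln <- lines[frames[[f]]]
    coords[, , f] <- cbind(as.numeric(substr(ln, 31, 38)),
                           as.numeric(substr(ln, 39, 46)),
                           as.numeric(substr(ln, 47, 54)))
  }
  sf_trajectory(coords, box = box)
}

read_xyz_trajectory <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na)) abort(sprintf("bad XYZ atom count at line %d", i))
    if (i + 1 + na > length(lines))
      abort(sprintf("truncated frame %d in XYZ file", length(frames) + 1))
    blk <- lines[(i + 2):(i + 1 + na)]
    m <- do.call(rbind, lapply(strsplit(trimws(blk), "\\s+"), function(tk)
      as.numeric(tk[2:4])))
    if (anyNA(m)) abort(sprintf("truncated frame %d in XYZ file",
                                length(frames) + 1))
    frames[[length(frames) + 1]] <- m
    i <- i + 2 + na
  }
  if (length(frames) == 0)
    return(sf_trajectory(array(0, c(0, 3, 0)), times = numeric(0)))
  na <- nrow(frames[[1]])
  if (!is.null(topology) && na != nrow(topology))
    abort("atom-count mismatch with topology")
  coords <- array(unlist(frames), c(na, 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  sf_trajectory(coords)
}

#' Write a trajectory as XYZ
#' @inheritParams write_pdb
#' @export
write_xyz <- function(trajectory, topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(trajectory))) {
    X <- frame_coords(trajectory, f)
    writeLines(as.character(nrow(topology)), con)
    writeLines(sprintf("frame %d t= %.6f", f, trajectory$times[f]), con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", topology$name,
                       X[, 1], X[, 2], X[, 3]), con)
  }
  invisible(path)
}

#' Write a trajectory as CHARMM-dialect DCD
#'
#' Binary DCD with Fortran record markers, a unit-cell record per frame and
#' float32 coordinates.
#' @inheritParams write_pdb
#' @export
write_dcd <- function(trajectory, topology, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    raw <- writer()
    writeBin(length(raw), con, size = 4)
    writeBin(raw, con)
    writeBin(length(raw), con, size = 4)
  }
  nf <- n_frames(trajectory)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- 1L          # unit-cell records present
  icntrl[20] <- 24L         # CHARMM version tag
  rec(function() c(writeBin(charToRaw("CORD"), raw()),
                   writeBin(icntrl, raw(), size = 4)))
  title <- formatC("sfpore trajectory", width = -80)
  rec(function() c(writeBin(1L, raw(), size = 4),
                   writeBin(charToRaw(title), raw())))
  rec(function() writeBin(nrow(topology), raw(), size = 4))
  for (f in seq_len(nf)) {
    b <- trajectory$box[min(f, nrow(trajectory$box)), ]
    cell <- c(b[1], 0, b[2], 0, 0, b[3])  # lower-triangle unit cell
    rec(function() writeBin(cell, raw(), size = 8))
    X <- frame_coords(trajectory, f)
    for (d in 1:3)
      rec(function() writeBin(as.numeric(X[, d]), raw(), size = 4))
  }
  invisible(path)
}

read_dcd_trajectory <- function(path, topology = NULL) {
  if (is.null(topology))
    abort("reading DCD requires a topology (atom metadata is not stored in DCD)")
  con <- file(path, "rb")
  on.exit(close(con))
  rec <- function() {
    n <- readBin(con, "integer", 1, size = 4)
    if (length(n) == 0) return(NULL)
    raw <- readBin(con, "raw", n)
    readBin(con, "integer", 1, size = 4)
    raw
  }
  hdr <- rec()
  if (is.null(hdr) || rawToChar(hdr[1:4]) != "CORD")
    abort("not a DCD file (missing CORD magic)")
  icntrl <- readBin(hdr[-(1:4)], "integer", 20, size = 4)
  nf <- icntrl[1]
  has_cell <- icntrl[11] == 1L
  rec()  # title
  na <- readBin(rec(), "integer", 1, size = 4)
  if (na != nrow(topology))
    abort(sprintf("atom-count mismatch: DCD has %d, topology has %d",
                  na, nrow(topology)))
  coords <- array(NA_real_, c(na, 3, nf))
  box <- matrix(NA_real_, nf, 3)
  for (f in seq_len(nf)) {
    if (has_cell) {
      cell <- readBin(rec(), "double", 6, size = 8)
      box[f, ] <- cell[c(1, 3, 6)]
    }
    for (d in 1:3) {
      r <- rec()
      if (is.null(r) || length(r) != 4L * na)
        abort(sprintf("truncated frame %d in DCD file", f))
      coords[, d, f] <- readBin(r, "double", na, size = 4)
    }
  }
  sf_trajectory(coords, box = box)
}

#' Write / read a topology as a plain-text atom table
#'
#' One atom per line (TSV): id, name, resname, resnum, chain, charge, sigma,
#' epsilon, role, x, y, z. Box, dielectric and variant ride along as `#`
#' header comments. Tethers, bonds and non-bonded overrides are part of the
#' model definition, not the interchange table.
#'
#' @param topology An [sf_topology].
#' @param path File path.
#' @export
write_topology_table <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# variant\t%s", attr(topology, "variant")),
    sprintf("# box\t%.6f\t%.6f\t%.6f", attr(topology, "box")[1],
            attr(topology, "box")[2], attr(topology, "box")[3]),
    sprintf("# eps_r\t%.6f", attr(topology, "eps_r")),
    sprintf("# cutoff\t%.6f", attr(topology, "cutoff"))), con)
  df <- topology[, c("id", "name", "resname", "resnum", "chain", "charge",
                     "sigma", "epsilon", "role", "x", "y", "z")]
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology_table
#' @export
read_topology_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key))]
    if (!length(ln)) return(NULL)
    strsplit(sub(paste0("# ", key, "\t"), "", ln[1]), "\t")[[1]]
  }
  df <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE,
                   na.strings = character(0))  # "NA" is the sodium bead name
  atoms <- tibble::as_tibble(df)
  atoms$anchor_x <- NA_real_; atoms$anchor_y <- NA_real_
  atoms$anchor_z <- NA_real_
  atoms$tether_k <- NA_real_; atoms$tether_r0 <- NA_real_
  atoms$mobile <- atoms$role %in% c("ion", "water-O")
  geom <- list(box = as.numeric(get("box")),
               eps_r = as.numeric(get("eps_r")),
               cutoff = as.numeric(get("cutoff")),
               wall_z = 1e6, wall_k = 0)
  atoms$id <- NULL
  new_sf_topology(atoms, geom$box, get("variant") %||% "unknown", geom)
}

#' Resolve an atom-selection expression
#'
#' A small selection language: `key value` clauses joined by `and` / `or`,
#' evaluated left to right. Keys: `chain`, `resnum`, `resname`, `name`,
#' `role`. Example: `"chain A and resnum 183 and role carboxylate-O"`.
#'
#' @param topology An [sf_topology].
#' @param expression Selection string (or an integer vector of atom ids,
#'   returned as-is).
#' @return An `sf_selection`: list with `expression` and sorted unique
#'   `indices`. Empty selections warn.
#' @export
select_atoms <- function(topology, expression) {
  if (is.numeric(expression)) {
    idx <- sort(unique(as.integer(expression)))
    if (any(idx < 1 | idx > nrow(topology)))
      abort("selection indices outside atom count")
    return(structure(list(expression = deparse(substitute(expression)),
                          indices = idx), class = "sf_selection"))
  }
  tokens <- strsplit(trimws(expression), "\\s+")[[1]]
  if (length(tokens) == 0) abort("empty selection expression")
  keys <- c("chain", "resnum", "resname", "name", "role")
  idx <- NULL
  op <- NULL
  i <- 1
  while (i <= length(tokens)) {
    tk <- tokens[i]
    if (tk %in% c("and", "or")) {
      if (is.null(idx) || i == length(tokens))
        abort(sprintf("syntax error at token %d ('%s'): dangling operator", i, tk))
      op <- tk
      i <- i + 1
      next
    }
    if (!tk %in% keys)
      abort(sprintf("syntax error at token %d ('%s'): expected one of %s",
                    i, tk, paste(keys, collapse = ", ")))
    if (i + 1 > length(tokens))
      abort(sprintf("syntax error at token %d: key '%s' missing a value", i, tk))
    val <- tokens[i + 1]
    col <- topology[[tk]]
    hit <- which(if (tk == "resnum") col == as.integer(val) else col == val)
    idx <- if (is.null(idx)) hit
           else if (identical(op, "or")) union(idx, hit)
           else intersect(idx, hit)
    op <- NULL
    i <- i + 2
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0)
    warn(paste0("selection '", expression, "' matched no atoms"))
  structure(list(expression = expression, indices = idx),
            class = "sf_selection")
}

#' @export
print.sf_selection <- function(x, ...) {
  cat(sprintf("<sf_selection> '%s': %d atoms\n", x$expression,
              length(x$indices)))
  invisible(x)
}

resolve_selection <- function(topology, sel) {
  if (inherits(sel, "sf_selection")) return(sel$indices)
  if (is.numeric(sel)) return(select_atoms(topology, sel)$indices)
  select_atoms(topology, sel)$indices
}

#' Write an analysis-result table as TSV
#'
#' Deterministic column order (as given), floats at fixed precision, header
#' row carrying units in the column names. Re-serialising a read-back table
#' is byte-identical.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param digits Fixed decimal places for numeric columns.
#' @export
write_tables <- function(x, path, digits = 4) {
  if (is.null(x)) abort("results must be non-null")
  df <- as.data.frame(x)
  for (cl in names(df))
    if (is.double(df[[cl]]))
      df[[cl]] <- formatC(df[[cl]], format = "f", digits = digits)
  tryCatch(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) abort(paste0("cannot write table: ", conditionMessage(e))))
  invisible(path)
}

#' @rdname write_tables
#' @export
read_tables <- function(path) {
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}
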