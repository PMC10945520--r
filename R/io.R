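# Readers and writers for the formats the pipeline touches: PDB / GRO
# topologies, multi-model PDB and DCD trajectories, TSV state-label tables,
# and volumetric grids in OpenDX and MRC/CCP4.

# residue names treated as lipids unless the caller overrides
DEFAULT_LIPID_NAMES <- c("POPC", "POPE", "POPG", "POPS", "DPPC", "DOPC",
                         "DOPE", "DMPC", "CHOL", "LIP")

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL",
                 "SUR", "GAT", "SIT")   # synthetic pseudo-residues

#' Read a topology from a PDB or GRO file
#'
#' Molecule kinds are inferred from residue names: names in `lipid_names`
#' become lipid molecules (one molecule per residue), everything else is
#' protein.  Residue names that are neither lipids nor standard amino
#' acids default to protein with a warning.  Residue numbering is taken
#' verbatim from the file.
#'
#' @param path PDB (`.pdb`) or GRO (`.gro`) file.
#' @param lipid_names character vector of lipid residue names.
#' @param radius van der Waals radius assigned to every atom, Angstrom
#'   (a single default suffices for bead models; supply a named vector
#'   keyed by atom name to differentiate).
#' @return an [sl_topology()].
#' @export
read_topology <- function(path, lipid_names = DEFAULT_LIPID_NAMES,
                          radius = 1.7) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    pdb = parse_pdb_atoms(path),
    gro = parse_gro_atoms(path),
    stopf("unsupported topology format '.%s' (use .pdb or .gro)", ext))
  if (nrow(df) == 0) stopf("no atoms parsed from %s", path)

  kind <- ifelse(df$resname %in% lipid_names, "lipid", "protein")
  unknown <- setdiff(unique(df$resname),
                     c(lipid_names, AMINO_ACIDS))
  if (length(unknown)) {
    warnf("unknown residue name(s) treated as protein: %s",
          paste(unknown, collapse = ", "))
  }
  lipid_id <- rep(NA_integer_, nrow(df))
  is_lip <- kind == "lipid"
  if (any(is_lip)) {
    key <- paste(df$chain[is_lip], df$resid[is_lip], df$resname[is_lip])
    lipid_id[is_lip] <- as.integer(factor(key, levels = unique(key)))
  }
  r <- if (length(radius) == 1 && is.null(names(radius))) {
    rep(radius, nrow(df))
  } else {
    out <- unname(radius[df$elety])
    out[is.na(out)] <- 1.7
    out
  }
  topo <- sl_topology(data.frame(
    eleno = df$eleno, elety = df$elety, resid = df$resid,
    resname = df$resname, chain = df$chain, kind = kind,
    lipid_id = lipid_id, radius = r, stringsAsFactors = FALSE))
  attr(topo, "coords") <- as.matrix(df[c("x", "y", "z")])
  topo
}

parse_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stopf("cannot parse PDB %s: %s",
                                            path, conditionMessage(e)))
  a <- pdb$atom
  data.frame(eleno = a$eleno, elety = a$elety, resid = a$resno,
             resname = a$resid,
             chain = ifelse(is.na(a$chain), "A", a$chain),
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

parse_gro_atoms <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stopf("truncated GRO file: %s", path)
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat)) stopf("GRO format error at line 2: bad atom count")
  if (length(lines) < nat + 3) {
    stopf("GRO format error: %d atoms declared, file has %d atom lines",
          nat, length(lines) - 3L)
  }
  rec <- lines[3:(nat + 2)]
  resid <- suppressWarnings(as.integer(substr(rec, 1, 5)))
  resname <- trimws(substr(rec, 6, 10))
  elety <- trimws(substr(rec, 11, 15))
  eleno <- suppressWarnings(as.integer(substr(rec, 16, 20)))
  x <- suppressWarnings(as.numeric(substr(rec, 21, 28))) * 10  # nm -> A
  y <- suppressWarnings(as.numeric(substr(rec, 29, 36))) * 10
  z <- suppressWarnings(as.numeric(substr(rec, 37, 44))) * 10
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) stopf("GRO format error at line %d", bad[1] + 2L)
  data.frame(eleno = eleno, elety = elety, resid = resid, resname = resname,
             chain = "A", x = x, y = y, z = z, stringsAsFactors = FALSE)
}

pdb_atom_lines <- function(atoms, coords, b = NULL, o = 1) {
  b <- b %||% rep(0, nrow(atoms))
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          atoms$eleno %% 100000L,
          substr(atoms$elety, 1, 4),
          substr(atoms$resname, 1, 3),
          substr(atoms$chain, 1, 1),
          atoms$resid %% 10000L,
          coords[, 1], coords[, 2], coords[, 3], o, pmin(b, 999.99))
}

cryst1_line <- function(box) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          box[1], box[2], box[3], 90, 90, 90)
}

#' Write a topology (with coordinates) as a single-model PDB
#'
#' Lipid molecules are written as distinct residues; protein subunits keep
#' their chain identifiers.
#'
#' @param topology an [sl_topology()].
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param path output file.
#' @param box optional length-3 box vector written as a CRYST1 record.
#' @export
write_topology_pdb <- function(topology, coords, path, box = NULL) {
  lines <- character()
  if (!is.null(box)) lines <- cryst1_line(box)
  lines <- c(lines, pdb_atom_lines(topology$atoms, coords), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a topology (with coordinates) as a GRO file
#'
#' GRO stores lengths in nm and carries no chain identifiers; residue
#' numbers and names are preserved.
#'
#' @inheritParams write_topology_pdb
#' @export
write_topology_gro <- function(topology, coords, path, box = NULL) {
  a <- topology$atoms
  lines <- c("synthetic system", sprintf("%5d", nrow(a)),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     a$resid %% 100000L, substr(a$resname, 1, 5),
                     substr(a$elety, 1, 5), a$eleno %% 100000L,
                     coords[, 1] / 10, coords[, 2] / 10, coords[, 3] / 10))
  box <- box %||% c(0, 0, 0)
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f",
                            box[1] / 10, box[2] / 10, box[3] / 10))
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param trajectory an [sl_trajectory()].
#' @param topology matching [sl_topology()].
#' @param path output file.
#' @param frames optional 0-based frame indices to write (default all).
#' @export
write_trajectory_pdb <- function(trajectory, topology, path, frames = NULL) {
  check_consistent(trajectory, topology)
  frames <- frames %||% (0:(n_frames(trajectory) - 1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(cryst1_line(trajectory$box[1, ]), con)
  for (i in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(pdb_atom_lines(topology$atoms,
                              frame_coords(trajectory, frames[i])), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a coordinate trajectory
#'
#' Multi-model PDB and DCD are supported (XTC is not readable here; convert
#' to DCD or PDB first).  Frames arrive in file order; the box is taken
#' from the PDB CRYST1 record or DCD unit-cell record when present,
#' otherwise from the `box` argument.
#'
#' @param path `.pdb` (multi-model) or `.dcd` file.
#' @param topology matching [sl_topology()]; atom counts must agree.
#' @param dt time per frame in ns (trajectory files carry no time metadata).
#' @param box fallback length-3 box vector, Angstrom.
#' @param id,condition trajectory identifier and condition tag.
#' @return an [sl_trajectory()].
#' @export
read_trajectory <- function(path, topology, dt = 1, box = NULL,
                            id = basename(path), condition = NA_character_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  nat <- nrow(topology$atoms)
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (ncol(xyz) != 3 * nat) {
      stopf("trajectory has %d atoms but topology has %d",
            ncol(xyz) / 3, nat)
    }
    nf <- nrow(xyz)
    coords <- array(NA_real_, c(nat, 3, nf))
    for (f in seq_len(nf)) {
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    }
    cl <- grep("^CRYST1", readLines(path), value = TRUE)
    if (length(cl) && is.null(box)) {
      box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                          substr(cl[1], 25, 33)))
    }
  } else if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (ncol(xyz) != 3 * nat) {
      stopf("trajectory has %d atoms but topology has %d",
            ncol(xyz) / 3, nat)
    }
    nf <- nrow(xyz)
    coords <- array(NA_real_, c(nat, 3, nf))
    for (f in seq_len(nf)) {
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    }
  } else if (ext == "xtc") {
    stopf("XTC reading is not supported; convert to DCD or multi-model PDB")
  } else {
    stopf("unsupported trajectory format '.%s'", ext)
  }
  if (is.null(box)) stopf("no box information in %s; supply box=", path)
  sl_trajectory(coords, box, dt, id = id, condition = condition)
}

#' Read a state-label table from TSV
#'
#' @param path TSV with header columns `traj_id`, `frame`, `state`.
#' @param vocabulary allowed labels (plus `"unassigned"`).
#' @return an [sl_state_labels()].
#' @export
read_state_labels <- function(path, vocabulary = c("closed", "open")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read_tsv(path)
  sl_state_labels(df, vocabulary = vocabulary)
}

#' Write a state-label table as TSV
#' @param labels an [sl_state_labels()].
#' @param path output file.
#' @export
write_state_labels <- function(labels, path) {
  write_tsv(as.data.frame(labels), path)
}

#' Write / read a volumetric grid
#'
#' OpenDX (`"dx"`) is plain text with the z index varying fastest; MRC/CCP4
#' (`"mrc"`) is binary mode-2 (float32) with the x index varying fastest.
#' Both writers record the grid origin (centre of the first voxel) and the
#' isotropic spacing in Angstrom, and both round-trip within 1e-5.
#'
#' @param grid an [sl_grid()].
#' @param path output file.
#' @param format `"dx"` or `"mrc"` (default from the file extension).
#' @export
write_grid <- function(grid, path, format = tools::file_ext(path)) {
  format <- tolower(format)
  switch(format,
         dx = write_grid_dx(grid, path),
         mrc = , ccp4 = , map = write_grid_mrc(grid, path),
         stopf("unsupported grid format '%s' (use dx or mrc)", format))
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path, format = tools::file_ext(path)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  format <- tolower(format)
  switch(format,
         dx = read_grid_dx(path),
         mrc = , ccp4 = , map = read_grid_mrc(path),
         stopf("unsupported grid format '%s' (use dx or mrc)", format))
}

write_grid_dx <- function(grid, path) {
  d <- dim(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX occupancy grid",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6g %.6g %.6g",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6g 0 0", grid$spacing),
    sprintf("delta 0 %.6g 0", grid$spacing),
    sprintf("delta 0 0 %.6g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  v <- as.vector(aperm(grid$values, c(3, 2, 1)))   # z fastest
  n3 <- (length(v) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(v[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(v)) {
    writeLines(paste(sprintf("%.9g", v[(n3 + 1):length(v)]), collapse = " "),
               con)
  }
  writeLines('attribute "dep" string "positions"', con)
  writeLines('object "density" class field', con)
}

read_grid_dx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  gp <- grep("gridpositions", lines, value = TRUE)
  if (!length(gp)) stopf("DX format error in %s: no gridpositions object", path)
  counts <- as.integer(strsplit(trimws(sub(".*counts", "", gp[1])),
                                "\\s+")[[1]])
  org_line <- grep("^origin", lines, value = TRUE)
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", org_line[1])),
                                "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- t(vapply(deltas, function(l) {
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]])
  }, numeric(3)))
  spacing <- max(dmat)
  start <- grep("data follows", lines)
  if (!length(start)) stopf("DX format error in %s: no data section", path)
  end <- grep("^attribute|^object \"", lines)
  end <- end[end > start[1]]
  end <- if (length(end)) min(end) - 1L else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(start[1] + 1):end]),
                                     "\\s+")))
  if (length(vals) != prod(counts)) {
    stopf("DX format error in %s: %d values for %d voxels",
          path, length(vals), prod(counts))
  }
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  sl_grid(arr, origin, spacing)
}

write_grid_mrc <- function(grid, path) {
  d <- dim(grid$values)
  v <- as.vector(grid$values)       # x fastest, matches column-major
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                             # nx ny nz
  wi(2L)                            # mode 2 = float32
  wi(c(0L, 0L, 0L))                 # nxstart...
  wi(d)                             # mx my mz
  wf(d * grid$spacing)              # cell dimensions A
  wf(c(90, 90, 90))                 # cell angles
  wi(c(1L, 2L, 3L))                 # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))    # dmin dmax dmean
  wi(c(1L, 0L))                     # ispg, nsymbt
  wi(rep(0L, 25))                   # extra
  wf(grid$origin)                   # MRC2014 origin (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)   # little-endian stamp
  wf(stats::sd(v))                  # rms
  wi(0L)                            # nlabl
  writeBin(raw(200 * 4), con)       # label block
  wf(v)
}

read_grid_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stopf("MRC format error in %s: truncated header",
                                    path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stopf("MRC mode %d unsupported (only mode 2 float32)", mode)
  ri(3)                             # nxstart
  m <- ri(3)                        # mx my mz
  cella <- rf(3)
  rf(3); ri(3); rf(3); ri(2); ri(25)
  origin <- rf(3)
  seek(con, 1024)
  nv <- prod(d)
  if (sz < 1024 + 4 * nv) stopf("MRC format error in %s: truncated data", path)
  v <- rf(nv)
  spacing <- cella[1] / m[1]
  sl_grid(array(v, dim = d), origin, spacing)
}

#' Write a PDB with a per-residue scalar in the B-factor column
#'
#' Projects a per-residue quantity (e.g. mean lipid-contact duration) onto
#' a structure for visualisation: every atom's B-factor is set to its
#' residue's scalar, clipped to `[0, 999.99]`.  Protein residues missing
#' from the table get 0 with a warning.
#'
#' @param topology an [sl_topology()].
#' @param coords n x 3 coordinate matrix.
#' @param per_residue data.frame with columns `chain`, `resid`, `value`.
#' @param path output PDB.
#' @export
write_bfactor_pdb <- function(topology, coords, per_residue, path) {
  a <- topology$atoms
  key <- paste(a$chain, a$resid)
  map <- stats::setNames(per_residue$value,
                         paste(per_residue$chain, per_residue$resid))
  b <- unname(map[key])
  miss <- is.na(b) & a$kind == "protein"
  if (any(miss)) {
    warnf("%d protein residues missing from scalar table; B set to 0",
          length(unique(key[miss])))
  }
  b[is.na(b)] <- 0
  if (any(b > 999.99)) {
    warnf("%d B-factor values clipped to 999.99", sum(b > 999.99))
  }
  b <- pmin(pmax(b, 0), 999.99)
  writeLines(c(pdb_atom_lines(a, coords, b = b), "END"), path)
  invisible(path)
}
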