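#' Read a molecular-liquid trajectory from GRO or extended-XYZ
#'
#' Native readers for the two supported text formats. GRO is the fixed-column
#' GROMACS coordinate format with one box-vector line per frame; extended XYZ
#' carries the box on the comment line as `Lattice="Lx 0 0 0 Ly 0 0 0 Lz"`.
#' Only cubic boxes are supported; a non-cubic box record raises an error.
#'
#' Hydroxyl topology is inferred from atom naming: names `OH`/`O` mark the
#' hydroxyl oxygen and `HO`/`H` the hydroxyl hydrogen, grouped by residue
#' (GRO) or by file order (XYZ). If naming is ambiguous, or carries no
#' hydroxyl sites, supply a side-car site map (see [read_site_map()]).
#'
#' @param path File path.
#' @param format One of `"gro"`, `"xyz"`.
#' @param site_map Optional `fluct_topology` from [read_site_map()] (or
#'   constructed directly) overriding name-based inference.
#' @param temperature,pressure Metadata attached to the trajectory (K, bar).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("gro", "xyz"), site_map = NULL,
                            temperature = NA_real_, pressure = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  parsed <- switch(format,
    gro = parse_gro(lines),
    xyz = parse_xyz(lines)
  )
  topo <- site_map
  if (is.null(topo)) {
    topo <- tryCatch(
      infer_hydroxyl_topology(parsed$names, parsed$resid),
      error = function(e) NULL
    )
  }
  trajectory(parsed$frames, topology = topo,
             temperature = temperature, pressure = pressure)
}

# GRO: title / natoms / natoms fixed-column atom lines / box line, repeated.
parse_gro <- function(lines) {
  frames <- list()
  names1 <- NULL
  resid1 <- NULL
  i <- 1L
  n_expected <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    if (i + 1L > length(lines)) stop("GRO format error: truncated header")
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms < 1L)
      stop("GRO format error: bad atom-count line at line ", i + 1L)
    if (!is.na(n_expected) && natoms != n_expected)
      stop("GRO format error: inconsistent atom counts across frames")
    n_expected <- natoms
    if (i + 1L + natoms + 1L > length(lines))
      stop("GRO format error: missing box record (truncated frame)")
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    resid <- as.integer(substr(atom_lines, 1L, 5L))
    aname <- trimws(substr(atom_lines, 11L, 15L))
    x <- as.numeric(substr(atom_lines, 21L, 28L))
    y <- as.numeric(substr(atom_lines, 29L, 36L))
    z <- as.numeric(substr(atom_lines, 37L, 44L))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop("GRO format error: unparseable coordinate columns")
    box <- as.numeric(strsplit(trimws(lines[i + 1L + natoms + 1L]),
                               "\\s+")[[1]])
    if (length(box) < 3L || anyNA(box[1:3]))
      stop("GRO format error: missing or unparseable box record")
    check_cubic_box(box)
    tm <- gro_title_time(title)
    frames[[length(frames) + 1L]] <- frame(cbind(x, y, z), box[1], time = tm)
    if (is.null(names1)) { names1 <- aname; resid1 <- resid }
    i <- i + natoms + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (length(frames) == 0L) stop("GRO format error: no frames found")
  list(frames = frames, names = names1, resid = resid1)
}

gro_title_time <- function(title) {
  m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(m) == 1L && nzchar(m))
    return(as.numeric(sub("t=\\s*", "", m)))
  0
}

# Extended XYZ: natoms / comment with Lattice="..." / atom lines, repeated.
parse_xyz <- function(lines) {
  frames <- list()
  names1 <- NULL
  i <- 1L
  n_expected <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natoms) || natoms < 1L)
      stop("XYZ format error: bad atom-count line at line ", i)
    if (!is.na(n_expected) && natoms != n_expected)
      stop("XYZ format error: inconsistent atom counts across frames")
    n_expected <- natoms
    if (i + 1L + natoms > length(lines))
      stop("XYZ format error: truncated frame")
    comment <- lines[i + 1L]
    lat <- regmatches(comment,
                      regexpr('Lattice="[^"]+"', comment))
    if (length(lat) != 1L || !nzchar(lat))
      stop("XYZ format error: missing Lattice box record on comment line")
    box9 <- as.numeric(strsplit(trimws(sub('Lattice="', "",
                                           sub('"$', "", lat))), "\\s+")[[1]])
    if (length(box9) != 9L || anyNA(box9))
      stop("XYZ format error: Lattice record must hold 9 numbers")
    off <- box9[c(2, 3, 4, 6, 7, 8)]
    if (any(abs(off) > 1e-9))
      stop("unsupported feature: non-orthorhombic box")
    check_cubic_box(box9[c(1, 5, 9)])
    tm <- 0
    tmm <- regmatches(comment, regexpr("Time=\\s*[-0-9.eE+]+", comment))
    if (length(tmm) == 1L && nzchar(tmm))
      tm <- as.numeric(sub("Time=\\s*", "", tmm))
    toks <- strsplit(trimws(lines[(i + 2L):(i + 1L + natoms)]), "\\s+")
    if (any(lengths(toks) < 4L))
      stop("XYZ format error: atom lines need name x y z")
    aname <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("XYZ format error: unparseable coordinates")
    frames[[length(frames) + 1L]] <- frame(xyz, box9[1], time = tm)
    if (is.null(names1)) names1 <- aname
    i <- i + natoms + 2L
  }
  if (length(frames) == 0L) stop("XYZ format error: no frames found")
  list(frames = frames, names = names1, resid = NULL)
}

check_cubic_box <- function(box3) {
  if (any(box3 <= 0)) stop("box record error: box edges must be positive")
  if (max(box3) - min(box3) > 1e-6 * max(box3))
    stop("unsupported feature: non-cubic box (Lx, Ly, Lz differ)")
  invisible(TRUE)
}

# Hydroxyl inference: per residue, exactly one O-like and one H-like name;
# when the format carries no residue grouping (XYZ), the i-th O pairs with
# the i-th H in file order.
infer_hydroxyl_topology <- function(names, resid) {
  is_o <- names %in% c("OH", "O")
  is_h <- names %in% c("HO", "H")
  if (!any(is_o) || !any(is_h))
    stop("no hydroxyl sites found by atom naming; supply a site map")
  if (is.null(resid)) {
    o_idx <- which(is_o)
    h_idx <- which(is_h)
    if (length(o_idx) != length(h_idx))
      stop("ambiguous hydroxyl naming (unequal O and H site counts); ",
           "supply a site map")
    return(topology(o_idx, h_idx))
  }
  mols <- unique(resid[is_o | is_h])
  o_idx <- integer(length(mols))
  h_idx <- integer(length(mols))
  for (k in seq_along(mols)) {
    oi <- which(is_o & resid == mols[k])
    hi <- which(is_h & resid == mols[k])
    if (length(oi) != 1L || length(hi) != 1L)
      stop("ambiguous hydroxyl naming in molecule ", mols[k],
           "; supply a site map")
    o_idx[k] <- oi
    h_idx[k] <- hi
  }
  topology(o_idx, h_idx)
}

#' Read a hydroxyl site map
#'
#' Side-car text format: one row per atom site, two whitespace-separated
#' columns `molecule_index role` with role in `{O, H, -}` (`-` with molecule
#' index 0 marks sites that are not hydroxyl sites). Row order matches the
#' atom-site order of the trajectory file.
#'
#' @param path File path.
#' @return A [topology()].
#' @export
read_site_map <- function(path) {
  tab <- utils::read.table(path, col.names = c("mol", "role"),
                           colClasses = c("integer", "character"))
  keep <- tab$role %in% c("O", "H")
  if (!any(keep)) stop("site map declares no hydroxyl sites")
  mols <- sort(unique(tab$mol[keep]))
  o_idx <- h_idx <- integer(length(mols))
  for (k in seq_along(mols)) {
    oi <- which(keep & tab$mol == mols[k] & tab$role == "O")
    hi <- which(keep & tab$mol == mols[k] & tab$role == "H")
    if (length(oi) != 1L || length(hi) != 1L)
      stop("site map must give exactly one O and one H per molecule")
    o_idx[k] <- oi
    h_idx[k] <- hi
  }
  topology(o_idx, h_idx)
}

#' Write a trajectory to GRO or extended-XYZ
#'
#' GRO coordinates are written with the format's fixed 3-decimal precision
#' (0.001 nm); XYZ uses full double precision. Files written here round-trip
#' through [read_trajectory()] to the declared precision.
#'
#' @param traj A [trajectory()] with at least one frame.
#' @param path Output file path.
#' @param format One of `"gro"`, `"xyz"`.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, format = c("gro", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "fluct_trajectory"))
  n_sites <- nrow(traj$frames[[1]]$positions)
  lab <- site_labels(traj$topology, n_sites)
  out <- character(0)
  for (f in traj$frames) {
    p <- f$positions
    if (format == "gro") {
      out <- c(out,
        sprintf("fluctnet frame t= %g", f$time),
        sprintf("%d", n_sites),
        sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                lab$mol, lab$res, lab$name, seq_len(n_sites),
                p[, 1], p[, 2], p[, 3]),
        sprintf("%12.6f%12.6f%12.6f", f$box_edge, f$box_edge, f$box_edge))
    } else {
      out <- c(out,
        sprintf("%d", n_sites),
        sprintf('Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Time=%g',
                f$box_edge, f$box_edge, f$box_edge, f$time),
        sprintf("%s %.10g %.10g %.10g", lab$name, p[, 1], p[, 2], p[, 3]))
    }
  }
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) stop("I/O error writing ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

site_labels <- function(topo, n_sites) {
  name <- rep("X", n_sites)
  mol <- seq_len(n_sites)
  if (!is.null(topo)) {
    name[topo$o_index] <- "OH"
    name[topo$h_index] <- "HO"
    mol <- rep(0L, n_sites)
    mol[topo$o_index] <- seq_len(topo$n_molecules)
    mol[topo$h_index] <- seq_len(topo$n_molecules)
    extra <- which(mol == 0L)
    if (length(extra)) mol[extra] <- topo$n_molecules + seq_along(extra)
  }
  list(mol = (mol - 1L) %% 100000L + 1L, res = rep("MOL", n_sites),
       name = name)
}

#' Write a hydroxyl site map
#'
#' Inverse of [read_site_map()]: one row per atom site.
#'
#' @param topo A [topology()].
#' @param n_sites Total atom-site count of the trajectory.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_site_map <- function(topo, n_sites, path) {
  mol <- rep(0L, n_sites)
  role <- rep("-", n_sites)
  mol[topo$o_index] <- seq_len(topo$n_molecules)
  role[topo$o_index] <- "O"
  mol[topo$h_index] <- seq_len(topo$n_molecules)
  role[topo$h_index] <- "H"
  writeLines(sprintf("%d %s", mol, role), path)
  invisible(path)
}
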