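# File formats: PDB (via bio3d), XYZ trajectories, two-column CV series,
# window manifests and PMF tables. Every artifact written by the pipelines
# carries a header with package version, seed and configuration hash.

.artifact_header <- function(seed = NA, config_hash = NA) {
  sprintf("# pmfpath %s | seed %s | config %s",
          as.character(utils::packageVersion("pmfpath")),
          format(seed), format(config_hash))
}

#' Read a PDB file
#'
#' Reads ATOM/HETATM records (coordinates in Angstrom) and returns a
#' topology skeleton (element, residue bookkeeping) plus a coordinate frame.
#'
#' @param path PDB file path.
#' @return list with `atoms` (data.frame: element, name, resid, resno, chain)
#'   and `frame` (an [md_frame()]).
#' @export
read_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop(sprintf("PDB parse error in '%s': %s",
                                                   path, conditionMessage(e))))
  a <- pdb$atom
  coords <- as.matrix(a[, c("x", "y", "z")])
  if (anyNA(coords)) stop(sprintf("PDB '%s': missing coordinates", path))
  list(atoms = data.frame(element = ifelse(is.na(a$elesy) | a$elesy == "",
                                           substr(trimws(a$elety), 1, 1), a$elesy),
                          name = a$elety, resid = a$resid, resno = a$resno,
                          chain = a$chain),
       frame = md_frame(unname(coords)))
}

#' Write a frame as a PDB file
#'
#' @param frame an [md_frame()].
#' @param path output file.
#' @param elements atom element symbols (recycled).
#' @param resid residue name.
#' @return the path, invisibly.
#' @export
write_pdb <- function(frame, path, elements = "C", resid = "LIG") {
  n <- nrow(frame$coords)
  el <- rep_len(elements, n)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(frame$coords)),
                   type = rep("ATOM", n), resno = rep(1, n),
                   resid = rep(resid, n), eleno = seq_len(n),
                   elety = paste0(el, seq_len(n)), elesy = el)
  invisible(path)
}

#' Write a trajectory (or frame list) in multi-frame XYZ format
#'
#' Plain-text XYZ: per frame an atom count line, a comment line carrying the
#' time stamp, then `element x y z` rows (full double precision).
#'
#' @param trajectory an `md_trajectory`, or a list of [md_frame()]s.
#' @param path output file.
#' @param elements element symbols (recycled over atoms).
#' @return the path, invisibly.
#' @export
write_xyz_traj <- function(trajectory, path, elements = "C") {
  frames <- if (inherits(trajectory, "md_trajectory"))
    lapply(seq_along(trajectory$times), function(i) get_frame(trajectory, i))
  else trajectory
  con <- file(path, "w"); on.exit(close(con))
  for (f in frames) {
    n <- nrow(f$coords)
    el <- rep_len(elements, n)
    writeLines(c(as.character(n), sprintf("t= %.17g ps", f$time)), con)
    writeLines(sprintf("%s %.17g %.17g %.17g", el,
                       f$coords[, 1], f$coords[, 2], f$coords[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path XYZ file.
#' @return list of [md_frame()]s (element symbols in attribute `elements`).
#' @export
read_xyz_traj <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1; ln <- 1
  while (ln <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 1)
      stop(sprintf("XYZ parse error at line %d: expected atom count", ln))
    if (ln + 1 + n > length(lines))
      stop(sprintf("XYZ parse error at line %d: truncated frame", ln))
    t <- suppressWarnings(as.numeric(sub("^t=\\s*", "",
                                         sub("\\s*ps\\s*$", "", lines[ln + 1]))))
    rows <- strsplit(trimws(lines[(ln + 2):(ln + 1 + n)]), "\\s+")
    bad <- which(vapply(rows, length, 0L) < 4)
    if (length(bad))
      stop(sprintf("XYZ parse error at line %d: need 'element x y z'", ln + 1 + bad[1]))
    m <- matrix(suppressWarnings(as.numeric(unlist(lapply(rows, `[`, 2:4)))),
                n, 3, byrow = TRUE)
    if (anyNA(m)) stop(sprintf("XYZ parse error near line %d: bad coordinate", ln + 2))
    f <- md_frame(m, time = if (is.na(t)) i - 1 else t)
    attr(f, "elements") <- vapply(rows, `[`, "", 1)
    frames[[i]] <- f
    i <- i + 1; ln <- ln + 2 + n
  }
  frames
}

#' Write a collective-variable time series as two-column text
#'
#' Layout consumed by the WHAM stage: `time_ps value` per line, `#` header.
#'
#' @param series data.frame `time`, `value`.
#' @param path output file.
#' @param header extra header lines (prefixed `#`).
#' @return the path, invisibly.
#' @export
write_cv_series <- function(series, path, header = character(0)) {
  con <- file(path, "w"); on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(sprintf("%.6f %.10g", series$time, series$value), con)
  invisible(path)
}

#' Read a two-column CV time series
#' @param path file written by [write_cv_series()].
#' @return data.frame `time`, `value`.
#' @export
read_cv_series <- function(path) {
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("time", "value"))
  d
}

#' Write an umbrella-window manifest
#'
#' One metadata line per window (`filename center k2`), the layout standard
#' WHAM implementations consume, preceded by `#` header lines recording the
#' CV unit and periodicity.
#'
#' @param windows list of sampled `umbrella_window`s.
#' @param dir output directory (series files are written alongside).
#' @param prefix file-name prefix.
#' @param seed,config_hash recorded in the header.
#' @return manifest path, invisibly.
#' @export
write_windows <- function(windows, dir, prefix = "window", seed = NA,
                          config_hash = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cv <- windows[[1]]$cv
  manifest <- file.path(dir, paste0(prefix, "_manifest.txt"))
  con <- file(manifest, "w"); on.exit(close(con))
  writeLines(.artifact_header(seed, config_hash), con)
  writeLines(sprintf("# unit %s periodic %s", cv$unit,
                     if (isTRUE(cv$periodic)) cv$period else "no"), con)
  for (w in windows) {
    fn <- file.path(dir, sprintf("%s_%03d.dat", prefix, w$index))
    write_cv_series(w$series, fn,
                    header = sprintf("center %g k2 %g", w$center, w$k2))
    writeLines(sprintf("%s %g %g", basename(fn), w$center, w$k2), con)
  }
  invisible(manifest)
}

#' Read umbrella windows from a manifest
#'
#' @param manifest path written by [write_windows()].
#' @param cv the `colvar` the series belong to.
#' @return list of `umbrella_window`s with series loaded.
#' @export
read_windows <- function(manifest, cv) {
  lines <- readLines(manifest)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(trimws(lines), "\\s+")
  lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    umbrella_window(center = as.numeric(p[2]), k2 = as.numeric(p[3]), cv = cv,
                    series = read_cv_series(file.path(dirname(manifest), p[1])),
                    index = i)
  })
}

#' Write a PMF profile as a two-column text table
#'
#' @param profile a [pmf_profile()].
#' @param path output file.
#' @param seed,config_hash recorded in the header.
#' @return the path, invisibly.
#' @export
write_pmf_table <- function(profile, path, seed = NA, config_hash = NA) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.artifact_header(seed, config_hash), con)
  writeLines(sprintf("# coordinate(%s) pmf(kcal/mol)", profile$unit), con)
  writeLines(sprintf("%.6f %.6f", profile$centers, profile$pmf), con)
  invisible(path)
}
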