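write_matrix_gz <- function(m, path) {
  con <- gzfile(path, "wt")
  on.exit(close(con))
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

read_matrix_gz <- function(path, integer = FALSE) {
  m <- as.matrix(utils::read.table(gzfile(path), sep = "\t",
                                   colClasses = if (integer) "integer" else "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write a simulation snapshot
#'
#' Saves the label lattice, the three concentration fields (gzipped TSV
#' arrays), the cell registry and link list (CSV), and a small YAML header
#' with the MCS clock and dimensions, under a common file prefix.
#'
#' @param state an `nc_state` object.
#' @param prefix file path prefix; files `<prefix>_sigma.tsv.gz`,
#'   `<prefix>_field_{A,S,I}.tsv.gz`, `<prefix>_cells.csv`,
#'   `<prefix>_links.csv`, `<prefix>_meta.yaml` are written.
#' @return character vector of the files written, invisibly.
#' @export
write_snapshot <- function(state, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  files <- c(
    sigma = paste0(prefix, "_sigma.tsv.gz"),
    A = paste0(prefix, "_field_A.tsv.gz"),
    S = paste0(prefix, "_field_S.tsv.gz"),
    I = paste0(prefix, "_field_I.tsv.gz"),
    cells = paste0(prefix, "_cells.csv"),
    links = paste0(prefix, "_links.csv"),
    meta = paste0(prefix, "_meta.yaml"))
  write_matrix_gz(state$sigma, files["sigma"])
  for (s in c("A", "S", "I")) write_matrix_gz(state$fields[[s]], files[[s]])
  write.csv(state$cells, files["cells"], row.names = FALSE)
  write.csv(as.data.frame(state$links), files["links"], row.names = FALSE)
  yaml::write_yaml(list(mcs = state$mcs,
                        lattice = dim(state$sigma),
                        field_dim = dim(state$fields$A),
                        contacts = apply(state$contacts, 1, paste, collapse = ",")),
                   files["meta"])
  invisible(files)
}

#' Read a simulation snapshot
#'
#' @param prefix the prefix used in [write_snapshot()].
#' @return an `nc_state` object.
#' @export
read_snapshot <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  cells <- read.csv(paste0(prefix, "_cells.csv"))
  cells$cil <- as.logical(cells$cil)
  links <- as.matrix(read.csv(paste0(prefix, "_links.csv")))
  if (!nrow(links)) links <- matrix(integer(0), 0, 2)
  colnames(links) <- c("i", "j")
  ctc <- meta$contacts
  contacts <- if (length(ctc)) {
    do.call(rbind, lapply(strsplit(unlist(ctc), ","), as.integer))
  } else matrix(integer(0), 0, 2)
  colnames(contacts) <- c("i", "j")
  st <- list(
    sigma = read_matrix_gz(paste0(prefix, "_sigma.tsv.gz"), integer = TRUE),
    cells = cells,
    fields = list(A = read_matrix_gz(paste0(prefix, "_field_A.tsv.gz")),
                  S = read_matrix_gz(paste0(prefix, "_field_S.tsv.gz")),
                  I = read_matrix_gz(paste0(prefix, "_field_I.tsv.gz"))),
    links = links, contacts = contacts,
    mcs = as.integer(meta$mcs))
  class(st) <- "nc_state"
  st
}

#' Render the cell configuration as a PNG
#'
#' NC cells orange, placodal cells red, medium black.
#'
#' @param state an `nc_state` object.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_state_png <- function(state, path) {
  sig <- state$sigma
  ty <- state$cells$type
  img <- array(0, c(nrow(sig), ncol(sig), 3))
  occ <- sig > 0
  nc <- occ; nc[occ] <- ty[sig[occ]] == 1
  pl <- occ & !nc
  r <- matrix(0, nrow(sig), ncol(sig)); g <- r; b <- r
  r[nc] <- 1; g[nc] <- 0.6
  r[pl] <- 0.85; g[pl] <- 0.08; b[pl] <- 0.08
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  png::writePNG(img, path)
  invisible(path)
}

#' Render a concentration field as a normalized heatmap PNG
#'
#' @param field numeric matrix (e.g. [core_field()] output).
#' @param path output PNG path.
#' @param max_value normalization maximum (default the field's maximum).
#' @return `path`, invisibly.
#' @export
render_field_png <- function(field, path, max_value = max(field)) {
  v <- if (max_value > 0) pmin(field / max_value, 1) else field * 0
  # black -> blue -> yellow -> white ramp
  img <- array(0, c(nrow(field), ncol(field), 3))
  img[, , 1] <- pmin(pmax(2 * v - 0.6, 0), 1)
  img[, , 2] <- pmin(pmax(1.6 * v - 0.3, 0), 1)
  img[, , 3] <- pmin(2 * pmin(v, 0.45), 1) * (1 - 0.6 * pmax(v - 0.6, 0))
  png::writePNG(img, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the resolved parameter dump, seed list, run length and an MD5
#' checksum inventory of the listed output files — enough to detect post-hoc
#' modification and to re-run the scenario bit-identically.
#'
#' @param dir output directory (manifest written as `manifest.yaml` inside).
#' @param params the resolved `nc_params` used.
#' @param seeds replicate seeds.
#' @param n_mcs run length.
#' @param files character vector of output file paths to checksum.
#' @return path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, params, seeds, n_mcs, files = character(0)) {
  files <- files[file.exists(files)]
  man <- list(
    package_version = as.character(utils::packageVersion("ncstreams")),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    seeds = as.integer(seeds),
    n_mcs = as.integer(n_mcs),
    params = lapply(unclass(params), function(v)
      if (is.matrix(v)) apply(v, 1, as.vector, simplify = FALSE) else v),
    files = if (length(files))
      as.list(stats::setNames(as.character(tools::md5sum(files)),
                              basename(files)))
    else list())
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Verify a run manifest
#'
#' Recomputes the MD5 checksums of the files listed in a manifest.
#'
#' @param dir directory containing `manifest.yaml` and the output files.
#' @return `TRUE` if all checksums match; otherwise a character vector naming
#'   the mismatching or missing files.
#' @export
verify_manifest <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  bad <- character(0)
  for (nm in names(man$files)) {
    f <- file.path(dir, nm)
    if (!file.exists(f)) { bad <- c(bad, paste0(nm, " (missing)")); next }
    if (!identical(as.character(tools::md5sum(f)[[1]]), man$files[[nm]]))
      bad <- c(bad, paste0(nm, " (checksum mismatch)"))
  }
  if (length(bad)) bad else TRUE
}
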