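#' Read and write MRC/MRCS image stacks
#'
#' Minimal MRC2014 support for mode-2 (32-bit float) image stacks, the
#' interchange format of particle stacks. `write_mrcs` stores a
#' `box x box x n` array with the pixel size recorded in the cell dimensions;
#' `read_mrcs` reads modes 0, 1, 2 and 6 and returns the array and pixel
#' size. Writes are atomic (write-then-rename).
#'
#' @param images `box x box x n` numeric array (a matrix is treated as one
#'   image).
#' @param path file path (`.mrc`/`.mrcs`).
#' @param pixel_size pixel size in Angstrom, stored in the header.
#' @return `read_mrcs` returns a list with `images` (array, float32
#'   precision) and `pixel_size`.
#' @export
write_mrcs <- function(images, path, pixel_size = 1) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1))
  d <- dim(images)
  atomic_write(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
    wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
    wi(d)                                   # nx ny nz
    wi(2)                                   # mode 2: float32
    wi(c(0, 0, 0))                          # nxstart nystart nzstart
    wi(d)                                   # mx my mz
    wf(d * pixel_size)                      # cella
    wf(c(90, 90, 90))                       # cellb
    wi(c(1, 2, 3))                          # mapc mapr maps
    wf(range(images))                       # dmin dmax
    wf(mean(images))                        # dmean
    wi(0)                                   # ispg
    wi(0)                                   # nsymbt
    writeBin(raw(100), con)                 # extra
    wf(c(0, 0, 0))                          # origin
    writeChar("MAP ", con, 4, eos = NULL)
    writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
    wf(sd(images))                          # rms
    wi(0)                                   # nlabl
    writeBin(raw(800), con)                 # labels
    writeBin(as.numeric(images), con, size = 4, endian = "little")
  })
}

#' @rdname write_mrcs
#' @export
read_mrcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3); mx <- ri(3)
  cella <- rf(3)
  if (any(d < 1)) stopf("corrupt MRC header in '%s'", path)
  seek(con, 92)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  n_vox <- prod(d)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n_vox, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n_vox, size = 2, endian = "little")),
    "2" = readBin(con, "numeric", n_vox, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n_vox, size = 2, signed = FALSE,
                             endian = "little")),
    stopf("unsupported MRC mode %d", mode))
  if (length(data) != n_vox) stopf("truncated MRC data in '%s'", path)
  list(images = array(data, d),
       pixel_size = if (mx[1] > 0 && cella[1] > 0) cella[1] / mx[1] else 1)
}

#' Read and write STAR metadata tables
#'
#' Minimal STAR loop support for RELION-style per-particle metadata: one
#' `data_` block with a `loop_` of named columns. Column order follows the
#' data frame; unknown columns round-trip untouched.
#'
#' @param df data frame; names become STAR labels (prefixed with `_` on
#'   write).
#' @param path file path.
#' @param block data block name (default `"particles"`).
#' @return `read_star` returns the data frame (numeric columns detected).
#' @export
write_star <- function(df, path, block = "particles") {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c("", paste0("data_", block), "", "loop_"), con)
    labels <- sprintf("_%s #%d", names(df), seq_along(df))
    writeLines(labels, con)
    body <- do.call(paste, c(lapply(df, format, trim = TRUE, digits = 15),
                             sep = "\t"))
    writeLines(body, con)
    writeLines("", con)
  })
}

#' @rdname write_star
#' @export
read_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (length(loop_at) == 0) stopf("no loop_ block in '%s'", path)
  i <- loop_at[1] + 1
  labels <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    labels <- c(labels, sub("^_", "", sub("\\s+#\\d+$", "", lines[i])))
    i <- i + 1
  }
  rows <- lines[seq.int(i, length(lines))]
  rows <- rows[nzchar(rows) & !startsWith(rows, "data_")]
  if (length(rows) == 0) stopf("empty STAR loop in '%s'", path)
  parts <- strsplit(rows, "[ \t]+")
  if (any(lengths(parts) != length(labels)))
    stopf("ragged STAR table in '%s'", path)
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- labels
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(num)) df[[j]] <- num
  }
  df
}

# RELION-style column names for the interchange metadata; simulator-truth
# columns are namespaced with "cf" so third-party tools ignore them.
.star_cols <- c(defocus_um = "rlnDefocusU", pixel_size = "rlnImagePixelSize",
                snr = "cfSnr", truth_node = "cfTruthNode",
                qw = "cfOrientQw", qx = "cfOrientQx", qy = "cfOrientQy",
                qz = "cfOrientQz")

#' Read and write a particle stack with metadata
#'
#' The on-disk form of a particle stack: an MRC/MRCS file with the images
#' plus a STAR table with per-particle metadata (defocus in Angstrom under
#' the RELION label, pixel size, and namespaced simulator-truth columns),
#' and a JSON provenance sidecar with the generating configuration and seed.
#' Float32 stacks round-trip bit-exactly.
#'
#' @param stack a `"particle_stack"`.
#' @param stack_path path of the MRC/MRCS file.
#' @param metadata_path path of the STAR file (default: same stem, `.star`).
#' @return `read_particle_stack` returns a `"particle_stack"`. Metadata rows
#'   must match the stack length; missing optional columns are defaulted
#'   with a warning.
#' @export
write_particle_stack <- function(stack, stack_path, metadata_path = NULL) {
  metadata_path <- metadata_path %||% sub("\\.mrcs?$", ".star", stack_path)
  write_mrcs(stack$images, stack_path, stack$pixel_size)
  df <- stack$meta
  df$defocus_um <- df$defocus_um * 1e4       # RELION stores defocus in Angstrom
  names(df) <- ifelse(names(df) %in% names(.star_cols),
                      .star_cols[names(df)], names(df))
  write_star(df, metadata_path)
  prov_path <- sub("\\.star$", ".json", metadata_path)
  atomic_write(prov_path, function(tmp)
    jsonlite::write_json(stack$provenance %||% list(), tmp, auto_unbox = TRUE,
                         digits = NA))
  invisible(c(stack = stack_path, metadata = metadata_path,
              provenance = prov_path))
}

#' @rdname write_particle_stack
#' @export
read_particle_stack <- function(stack_path, metadata_path = NULL) {
  metadata_path <- metadata_path %||% sub("\\.mrcs?$", ".star", stack_path)
  mrc <- read_mrcs(stack_path)
  if (length(dim(mrc$images)) != 3 || dim(mrc$images)[1] != dim(mrc$images)[2])
    stopf("'%s' is not a square image stack", stack_path)
  ni <- dim(mrc$images)[3]
  df <- read_star(metadata_path)
  if (nrow(df) != ni)
    stopf("metadata has %d rows but stack has %d images", nrow(df), ni)
  back <- setNames(names(.star_cols), .star_cols)
  names(df) <- ifelse(names(df) %in% names(back), back[names(df)], names(df))
  if ("defocus_um" %in% names(df)) {
    df$defocus_um <- df$defocus_um / 1e4
  } else {
    warning("metadata lacks a defocus column; defaulting to 1.75 um")
    df$defocus_um <- 1.75
  }
  if (!"pixel_size" %in% names(df)) {
    warning("metadata lacks a pixel-size column; using the MRC header value")
    df$pixel_size <- mrc$pixel_size
  }
  prov_path <- sub("\\.star$", ".json", metadata_path)
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path) else NULL
  structure(list(images = mrc$images, meta = df,
                 pixel_size = df$pixel_size[1], box_size = dim(mrc$images)[1],
                 provenance = prov),
            class = "particle_stack")
}

#' Serialize a path to a directory
#'
#' A path is stored as one CSV of bead coordinates per node
#' (`node_001.csv`, ... with columns x, y, z, radius, electrons) plus a JSON
#' manifest recording node order, path parameters and the bead-table
#' version.
#'
#' @param path a [make_path()] object.
#' @param dir destination directory (created if needed).
#' @return `read_path` returns the [make_path()] object.
#' @export
write_path <- function(path, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- path_length(path)
  files <- sprintf("node_%03d.csv", seq_len(m))
  for (i in seq_len(m)) {
    nd <- path$nodes[[i]]
    df <- data.frame(x = nd$positions[, 1], y = nd$positions[, 2],
                     z = nd$positions[, 3], radius = nd$radii,
                     electrons = nd$electrons)
    atomic_write(file.path(dir, files[i]),
                 function(tmp) write.csv(df, tmp, row.names = FALSE))
  }
  manifest <- list(n_nodes = m, s_values = path$s_values, node_files = files,
                   bead_table = "zamyatnin-1972-v1")
  atomic_write(file.path(dir, "manifest.json"), function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA))
  invisible(dir)
}

#' @rdname write_path
#' @export
read_path <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  nodes <- lapply(manifest$node_files, function(f) {
    df <- read.csv(file.path(dir, f))
    conformation(as.matrix(df[, c("x", "y", "z")]), df$radius, df$electrons)
  })
  make_path(nodes)
}

#' Serialize a log-likelihood matrix
#'
#' CSV export with image and node identifiers (one row per image, columns
#' `image_id`, `node_<m>...`, and the round-1 values as `r1_node_<m>` when
#' present), plus a JSON record of the marginalization configuration so
#' posterior runs are reproducible.
#'
#' @param llmat a `"loglik_matrix"`.
#' @param path CSV path; the config is written next to it with extension
#'   `.json`.
#' @return `read_loglik_matrix` returns the `"loglik_matrix"`.
#' @export
write_loglik_matrix <- function(llmat, path) {
  df <- data.frame(image_id = llmat$image_ids)
  v <- llmat$values
  colnames(v) <- sprintf("node_%d", llmat$node_ids)
  df <- cbind(df, v)
  if (!is.null(llmat$round1)) {
    r1 <- llmat$round1
    colnames(r1) <- sprintf("r1_node_%d", llmat$node_ids)
    df <- cbind(df, r1)
  }
  atomic_write(path, function(tmp) write.csv(df, tmp, row.names = FALSE))
  cfg <- llmat$config
  if (!is.null(cfg)) {
    atomic_write(sub("\\.csv$", ".json", path), function(tmp)
      jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                           null = "null"))
  }
  invisible(path)
}

#' @rdname write_loglik_matrix
#' @export
read_loglik_matrix <- function(path) {
  df <- read.csv(path)
  node_cols <- grep("^node_", names(df), value = TRUE)
  r1_cols <- grep("^r1_node_", names(df), value = TRUE)
  out <- as_loglik_matrix(as.matrix(df[, node_cols, drop = FALSE]))
  out$image_ids <- df$image_id
  out$node_ids <- as.integer(sub("^node_", "", node_cols))
  if (length(r1_cols)) out$round1 <- unname(as.matrix(df[, r1_cols, drop = FALSE]))
  cfg_path <- sub("\\.csv$", ".json", path)
  if (file.exists(cfg_path)) out$config <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  out
}

#' Serialize a profile summary
#'
#' Writes the node-wise summary as CSV (columns `node`, `s`, `mean`, `ci5`,
#' `ci95`, `r_hat`) and, alongside it, a JSON version including the spline
#' knots.
#'
#' @param summary a [expected_profile()] result.
#' @param path CSV path.
#' @export
write_profile_summary <- function(summary, path) {
  df <- data.frame(node = seq_along(summary$s), s = summary$s,
                   mean = summary$mean_profile, ci5 = summary$ci_low,
                   ci95 = summary$ci_high, r_hat = summary$r_hat)
  atomic_write(path, function(tmp) write.csv(df, tmp, row.names = FALSE))
  atomic_write(sub("\\.csv$", ".json", path), function(tmp)
    jsonlite::write_json(list(s = summary$s, mean = summary$mean_profile,
                              ci5 = summary$ci_low, ci95 = summary$ci_high,
                              r_hat = summary$r_hat, shift = summary$shift),
                         tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}
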