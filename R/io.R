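# Plain-text / standard-format I/O: trees as CSV, binary projections as
# PNG, view geometries as YAML, reports as JSON, surfaces as legacy VTK
# (see tube_surface.R). One tree or projection bundle per file set, so
# every pipeline stage can be read and written standalone.

#' Write / read a coronary tree as CSV
#'
#' Long format with columns `branch`, `point`, `x`, `y`, `z`, `r`;
#' lesion annotations (branch, t0, severity, sigma) are stored in
#' commented header lines so the file round-trips the stenosis metadata.
#'
#' @param tree a [coronary_tree()].
#' @param path file path.
#' @return `path` (write) or the reconstructed tree (read).
#' @export
write_tree_csv <- function(tree, path) {
  M <- dim(tree)[1]; N <- dim(tree)[2]
  bn <- attr(tree, "branch_names")
  df <- do.call(rbind, lapply(seq_len(M), function(m)
    data.frame(branch = bn[m], point = seq_len(N),
               x = tree[m, , 1], y = tree[m, , 2], z = tree[m, , 3],
               r = tree[m, , 4])))
  con <- file(path, "w"); on.exit(close(con))
  for (l in attr(tree, "lesions"))
    writeLines(sprintf("# lesion %s %.17g %.17g %.17g",
                       l$branch, l$t0, l$severity, l$sigma), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_csv
#' @export
read_tree_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# lesion ", lines, value = TRUE)
  lesions <- lapply(hdr, function(h) {
    f <- strsplit(sub("^# lesion ", "", h), " ")[[1]]
    stenosis_spec(as.numeric(f[2]), as.numeric(f[3]), as.numeric(f[4]),
                  branch = f[1])
  })
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  bn <- unique(df$branch)
  N <- sum(df$branch == bn[1])
  dat <- array(0, c(length(bn), N, 4))
  for (m in seq_along(bn)) {
    sub <- df[df$branch == bn[m], ]
    sub <- sub[order(sub$point), ]
    dat[m, , ] <- as.matrix(sub[, c("x", "y", "z", "r")])
  }
  coronary_tree(dat, branch_names = bn,
                lesions = if (length(lesions)) lesions else NULL)
}

#' Write / read a binary projection image as PNG
#'
#' 8-bit grayscale, vessel = 255, background = 0.
#'
#' @param image binary matrix.
#' @param path file path.
#' @return `path` (write) or a binary 0/1 matrix (read).
#' @export
write_projection_png <- function(image, path) {
  png::writePNG(matrix(as.numeric(image), nrow(image), ncol(image)), path)
  invisible(path)
}

#' @rdname write_projection_png
#' @export
read_projection_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  (img > 0.5) * 1L
}

#' Write / read view geometries as YAML
#'
#' One document with a list of views, each holding the five defining
#' parameters (`theta`, `phi`, `SOD`, `SID`, `pixel_pitch`,
#' `image_size`); derived quantities (source, detector frame) are
#' recomputed on read.
#'
#' @param views list of [view_geometry()].
#' @param path file path.
#' @return `path` (write) or the list of views (read).
#' @export
write_views_yaml <- function(views, path) {
  yaml::write_yaml(lapply(views, function(v)
    list(theta = v$theta, phi = v$phi, SOD = v$SOD, SID = v$SID,
         pixel_pitch = v$pixel_pitch, image_size = v$image_size)), path)
  invisible(path)
}

#' @rdname write_views_yaml
#' @export
read_views_yaml <- function(path) {
  lapply(yaml::read_yaml(path), function(v)
    view_geometry(v$theta, v$phi, v$SOD, v$SID, v$pixel_pitch,
                  v$image_size))
}

#' Write an evaluation report as JSON
#'
#' @param x a list or data frame of metrics.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Run a generation / projection / evaluation pipeline
#'
#' Small orchestration layer over the package stages, writing each
#' stage's artifacts under `out/<stage>/` in the plain-text formats
#' above. A stage whose output directory already exists is skipped, so
#' deleting one stage's folder and re-running resumes from there. The
#' run configuration (seed included) is persisted as YAML next to the
#' outputs, and per-stage seeds are derived deterministically from the
#' root seed.
#'
#' @param out output root directory.
#' @param n_trees number of trees to generate.
#' @param config a [generator_config()].
#' @param sampler a [view_sampler()].
#' @param seed root seed.
#' @return invisibly, a list of per-stage artifact paths.
#' @export
run_pipeline <- function(out, n_trees = 5L, config = generator_config(),
                         sampler = view_sampler(), seed = 1L) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(seed = seed, n_trees = n_trees,
                        N = config$N, M = config$M,
                        views = sampler$views_per_tree,
                        inputs = sampler$inputs_per_sample,
                        image_size = sampler$image_size), file.path(out, "run.yaml"))
  stage_seed <- function(stage) (seed * 131L + sum(utf8ToInt(stage))) %% 2147483647L
  gen_dir <- file.path(out, "trees")
  if (!dir.exists(gen_dir)) {
    dir.create(gen_dir)
    old <- get_rng_state(); set.seed(stage_seed("generate"))
    for (i in seq_len(n_trees))
      write_tree_csv(generate_tree(config),
                     file.path(gen_dir, sprintf("tree_%03d.csv", i)))
    restore_rng_state(old)
  }
  proj_dir <- file.path(out, "projections")
  if (!dir.exists(proj_dir)) {
    dir.create(proj_dir)
    old <- get_rng_state(); set.seed(stage_seed("project"))
    for (f in list.files(gen_dir, full.names = TRUE)) {
      tree <- read_tree_csv(f)
      pset <- build_projection_set(tree, sampler)
      stem <- sub("[.]csv$", "", basename(f))
      for (k in seq_along(pset$images))
        write_projection_png(pset$images[[k]],
                             file.path(proj_dir, sprintf("%s_view%d.png", stem, k)))
      write_views_yaml(pset$views, file.path(proj_dir, paste0(stem, ".yaml")))
    }
    restore_rng_state(old)
  }
  eval_dir <- file.path(out, "evaluation")
  if (!dir.exists(eval_dir)) {
    dir.create(eval_dir)
    reports <- lapply(list.files(gen_dir, full.names = TRUE), function(f) {
      tree <- read_tree_csv(f)
      metrics_report(tree, tree)         # identity evaluation (sanity)
    })
    write_report_json(aggregate_metrics(reports),
                      file.path(eval_dir, "summary.json"))
  }
  invisible(list(trees = gen_dir, projections = proj_dir,
                 evaluation = eval_dir))
}
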