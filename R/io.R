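fmt_num <- function(x) {
  # shortest round-trip decimal text
  vapply(x, function(v) trimws(formatC(v, digits = 17, format = "g")), "")
}

#' Read and write time-series experiment CSVs
#'
#' The interchange dialect: a header line with `time`, then `y:<name>`
#' output columns and `u:<name>` input columns, plus an optional integer
#' `experiment` column grouping rows into suite members. Time must be
#' strictly increasing and uniformly spaced within each experiment.
#'
#' @param path file path.
#' @return `read_timeseries()` returns an [experiment_suite()].
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cn <- names(df)
  if (!("time" %in% cn))
    stop("read_timeseries: missing 'time' column in header of ", path)
  ycols <- grep("^y:", cn, value = TRUE)
  ucols <- grep("^u:", cn, value = TRUE)
  if (length(ycols) == 0L)
    stop("read_timeseries: no 'y:' output columns in ", path)
  bad <- which(!stats::complete.cases(df[, c("time", ycols, ucols)]))
  if (length(bad))
    stop("read_timeseries: NaN/missing cells at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  groups <- if ("experiment" %in% cn) split(seq_len(nrow(df)), df$experiment)
            else list(seq_len(nrow(df)))
  trajs <- lapply(groups, function(idx) {
    t <- as.numeric(df$time[idx])
    d <- diff(t)
    if (any(d <= 0))
      stop("read_timeseries: time not strictly increasing at row ",
           idx[which(d <= 0)[1L] + 1L])
    if ((max(d) - min(d)) > 1e-6 * mean(d))
      stop("read_timeseries: non-uniform sampling at row ",
           idx[which.max(abs(d - mean(d))) + 1L])
    Y <- as.matrix(df[idx, ycols, drop = FALSE])
    U <- if (length(ucols)) as.matrix(df[idx, ucols, drop = FALSE])
         else matrix(0, length(idx), 0L)
    colnames(Y) <- sub("^y:", "", ycols)
    if (length(ucols)) colnames(U) <- sub("^u:", "", ucols)
    new_trajectory(t, Y, U)
  })
  experiment_suite(unname(trajs),
                   output_names = sub("^y:", "", ycols),
                   input_names = sub("^u:", "", ucols))
}

#' @rdname read_timeseries
#' @param suite an [experiment_suite()].
#' @export
write_timeseries <- function(suite, path) {
  multi <- length(suite$trajectories) > 1L
  header <- c(if (multi) "experiment", "time",
              paste0("y:", suite$output_names),
              paste0("u:", suite$input_names))
  lines <- paste(header, collapse = ",")
  for (k in seq_along(suite$trajectories)) {
    tr <- suite$trajectories[[k]]
    block <- cbind(fmt_num(tr$t),
                   matrix(fmt_num(tr$Y), nrow(tr$Y)),
                   if (ncol(tr$U)) matrix(fmt_num(tr$U), nrow(tr$U)))
    if (multi) block <- cbind(as.character(k), block)
    lines <- c(lines, apply(block, 1L, paste, collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

rf_to_json <- function(e) list(num = as.numeric(e$num), den = as.numeric(e$den))

tfm_to_json <- function(tm) {
  lapply(seq_len(tm$rows), function(i)
    lapply(seq_len(tm$cols), function(j) rf_to_json(tm_entry(tm, i, j))))
}

#' Read and write DSF JSON files
#'
#' Serializes a dynamical structure function as
#' `{"format":"dsf-json/1","domain":"s"|"z","dt":null|number,
#' "outputs":[...],"inputs":[...],"Q":grid,"P":grid}` where each grid entry
#' is `{"num":[...],"den":[...]}` in descending powers with monic
#' denominators. Q diagonal entries must be exactly `{"num":[0],"den":[1]}`.
#' Round trips are coefficient-exact.
#'
#' @param x a `dsf` (continuous) or `discrete_dsf` (shared sampling
#'   interval).
#' @param path file path.
#' @return `read_dsf_json()` returns a `dsf` (with `dt` set for z-domain
#'   files).
#' @export
write_dsf_json <- function(x, path) {
  if (inherits(x, "discrete_dsf")) {
    zz <- ddsf_to_tfm(x, check_dt = TRUE)
    obj <- list(format = "dsf-json/1", domain = "z", dt = zz$dt,
                outputs = x$output_names, inputs = x$input_names,
                Q = tfm_to_json(zz$Q), P = tfm_to_json(zz$P))
  } else if (inherits(x, "dsf")) {
    domain <- x$Q$var
    obj <- list(format = "dsf-json/1", domain = domain, dt = x$dt,
                outputs = x$Q$row_names, inputs = x$P$col_names,
                Q = tfm_to_json(x$Q), P = tfm_to_json(x$P))
  } else stop("write_dsf_json: not a dsf or discrete_dsf")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_dsf_json
#' @export
read_dsf_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("format", "domain", "outputs", "inputs", "Q", "P")
  for (f in need) if (is.null(obj[[f]]))
    stop("read_dsf_json: missing field /", f, " in ", path)
  if (!identical(obj$format, "dsf-json/1"))
    stop("read_dsf_json: /format is not 'dsf-json/1'")
  var <- obj$domain
  if (!var %in% c("s", "z")) stop("read_dsf_json: /domain must be 's' or 'z'")
  outs <- unlist(obj$outputs); ins <- unlist(obj$inputs)
  p <- length(outs); m <- length(ins)
  parse_grid <- function(grid, rows, cols, name) {
    if (length(grid) != rows) stop("read_dsf_json: /", name, " has ",
                                   length(grid), " rows, expected ", rows)
    ent <- vector("list", rows * cols)
    for (i in seq_len(rows)) {
      if (length(grid[[i]]) != cols)
        stop("read_dsf_json: /", name, "/", i - 1L, " has ",
             length(grid[[i]]), " entries, expected ", cols)
      for (j in seq_len(cols)) {
        e <- grid[[i]][[j]]
        if (is.null(e$num) || is.null(e$den))
          stop("read_dsf_json: /", name, "/", i - 1L, "/", j - 1L,
               " missing num/den")
        den <- as.numeric(unlist(e$den))
        if (abs(den[1L] - 1) > 0)
          stop("read_dsf_json: /", name, "/", i - 1L, "/", j - 1L,
               " denominator not monic")
        ent[[(i - 1L) * cols + j]] <- rf(as.numeric(unlist(e$num)), den, var)
      }
    }
    ent
  }
  Qe <- parse_grid(obj$Q, p, p, "Q")
  Pe <- parse_grid(obj$P, p, m, "P")
  for (i in seq_len(p)) {
    if (!rf_is_zero(Qe[[(i - 1L) * p + i]]))
      stop("read_dsf_json: /Q/", i - 1L, "/", i - 1L,
           " diagonal entry is not zero")
  }
  Q <- tfm(Qe, p, p, outs, outs, var = var)
  P <- tfm(Pe, p, m, outs, ins, var = var)
  suppressWarnings(new_dsf(Q, P, dt = obj$dt))
}

#' Write a fit or crosstalk report as JSON
#'
#' @param report a `fit_report` or `crosstalk_report`.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  if (inherits(report, "crosstalk_report")) {
    obj <- list(kind = "crosstalk-report/1", tol = report$tol,
                norm = report$norm,
                labels = apply(report$labels, 1L, as.list, simplify = FALSE),
                gains = apply(report$gains, 1L, as.list, simplify = FALSE),
                normalized_gains = apply(report$normalized_gains, 1L,
                                         as.list, simplify = FALSE))
  } else {
    obj <- c(list(kind = "fit-report/1"), unclass(report))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Export a DSF as a directed graph (DOT or GraphML)
#'
#' Nodes are measured outputs; a directed edge `j -> i` is written for each
#' retained entry `Q_ij` (meaning output `j` causally influences output
#' `i`), with attributes `sign` (`+`, `-`, `+-`), normalized gain, and a
#' class label when a [classify_edges()] report is supplied. The file header
#' states the direction convention.
#'
#' @param dsf a `dsf` object.
#' @param path output file.
#' @param format `"dot"` or `"graphml"`.
#' @param report optional `crosstalk_report` for class labels/gains.
#' @param s_grid,tol passed to [structure_report()] for support/signs.
#' @export
export_graph <- function(dsf, path, format = c("dot", "graphml"),
                         report = NULL, s_grid = 10^seq(-4, 1, length.out = 25),
                         tol = 1e-2) {
  format <- match.arg(format)
  sr <- structure_report(dsf, s_grid = s_grid, tol = tol)
  p <- dsf$Q$rows
  nodes <- dsf$Q$row_names
  gains <- if (!is.null(report)) report$normalized_gains
           else sr$max_magnitude / max(sr$max_magnitude, .Machine$double.xmin)
  sign_chr <- c(activating = "+", repressing = "-", mixed = "+-")
  edges <- list()
  for (i in seq_len(p)) for (j in seq_len(p)) {
    keep <- if (!is.null(report)) report$labels[i, j] %in%
              c("crosstalk", "designed-active", "gain-mismatch")
            else sr$support[i, j]
    if (!isTRUE(keep)) next
    sgn <- sign_chr[sr$signs[i, j]]
    edges[[length(edges) + 1L]] <- list(
      from = nodes[j], to = nodes[i],
      sign = if (is.na(sgn)) "?" else unname(sgn),
      gain = unname(gains[i, j]),
      class = if (!is.null(report)) report$labels[i, j] else "present")
  }
  if (format == "dot") {
    lines <- c("// edge j -> i means: output j causally influences output i (Q_ij)",
               "digraph dsf {")
    for (nd in nodes) lines <- c(lines, sprintf("  \"%s\";", nd))
    for (e in edges)
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [sign=\"%s\", gain=\"%s\", class=\"%s\"];",
        e$from, e$to, e$sign, fmt_num(e$gain), e$class))
    lines <- c(lines, "}")
  } else {
    esc <- function(s) gsub("&", "&amp;", s, fixed = TRUE)
    lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<!-- edge j to i means: output j causally influences output i (Q_ij) -->",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"sign\" for=\"edge\" attr.name=\"sign\" attr.type=\"string\"/>",
      "  <key id=\"gain\" for=\"edge\" attr.name=\"gain\" attr.type=\"double\"/>",
      "  <key id=\"class\" for=\"edge\" attr.name=\"class\" attr.type=\"string\"/>",
      "  <graph id=\"dsf\" edgedefault=\"directed\">")
    for (nd in nodes)
      lines <- c(lines, sprintf("    <node id=\"%s\"/>", esc(nd)))
    for (k in seq_along(edges)) {
      e <- edges[[k]]
      lines <- c(lines, sprintf("    <edge id=\"e%d\" source=\"%s\" target=\"%s\">", k, esc(e$from), esc(e$to)),
                 sprintf("      <data key=\"sign\">%s</data>", e$sign),
                 sprintf("      <data key=\"gain\">%s</data>", fmt_num(e$gain)),
                 sprintf("      <data key=\"class\">%s</data>", e$class),
                 "    </edge>")
    }
    lines <- c(lines, "  </graph>", "</graphml>")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write kernel responses to CSV
#'
#' Companion export to [export_graph()]: columns `time` then `Q:i:j` for each
#' off-diagonal entry, sampled on the supplied grid.
#'
#' @param dsf a continuous-time `dsf`.
#' @param path output file.
#' @param t_grid sampling grid for the kernels.
#' @export
write_kernels_csv <- function(dsf, path, t_grid) {
  kr <- kernel_matrix(dsf, t_grid)
  p <- dsf$Q$rows
  cols <- list(time = fmt_num(kr$t_grid))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    cols[[sprintf("Q:%d:%d", i, j)]] <- fmt_num(kr$values[i, j, ])
  }
  lines <- c(paste(names(cols), collapse = ","),
             apply(do.call(cbind, cols), 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
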