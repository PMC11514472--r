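#' Assembly contiguity statistics (Nx / Lx)
#'
#' `Nx` is the length of the smallest piece in the minimal
#' descending-sorted prefix whose sum reaches `x%` of the total;
#' `Lx` is that prefix's size.
#'
#' @param lengths positive piece lengths in bp.
#' @param x percentages to evaluate.
#' @return data.frame with columns `x`, `Nx`, `Lx`.
#' @examples
#' contiguityStats(c(50, 40, 10))  # N50 = 50, L50 = 1; N90 = 40, L90 = 2
#' @export
contiguityStats <- function(lengths, x = c(10, 30, 50, 70, 90)) {
  if (length(lengths) == 0L) stop("at least one length is required")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(s)
  total <- cs[length(cs)]
  k <- vapply(x, function(p) which(cs >= p / 100 * total)[1], 1L)
  data.frame(x = x, Nx = s[k], Lx = k)
}

#' Assembly quality ratios
#'
#' The CC ratio is scaffolds over chromosomes. The structural error
#' ratio is the summed translocation and inversion lengths over the
#' corrected genome length (excluding redundant/leftover sequence), and
#' decomposes exactly into the per-category ratios on that same
#' denominator. The per-category rates are *also* reported against the
#' uncorrected genome size (the convention used for per-iteration error
#' tracking), and the anchor rate is the input contig size over the
#' uncorrected genome size, as a percentage. Each denominator is
#' surfaced explicitly in the output.
#'
#' @param nScaffolds,nChromosomes scaffold and chromosome counts.
#' @param transLengths,invLengths per-error lengths in bp (possibly
#'   empty).
#' @param lgCorrected corrected genome length excluding redundant
#'   sequence, bp.
#' @param lgUncorrected genome size before correction, bp (defaults to
#'   `lgCorrected`).
#' @param lContig total input contig size, bp (defaults to
#'   `lgUncorrected`).
#' @return named list of ratios and their denominators.
#' @examples
#' qualityRatios(24, 24, transLengths = 100, invLengths = 50,
#'               lgCorrected = 1000)
#' @export
qualityRatios <- function(nScaffolds, nChromosomes,
                          transLengths = numeric(),
                          invLengths = numeric(),
                          lgCorrected, lgUncorrected = lgCorrected,
                          lContig = lgUncorrected) {
  if (nChromosomes <= 0) stop("chromosome count must be positive")
  if (lgCorrected <= 0 || lgUncorrected <= 0)
    stop("genome lengths must be positive")
  sumT <- sum(transLengths); sumI <- sum(invLengths)
  rT <- sumT / lgCorrected
  rI <- sumI / lgCorrected
  list(
    cc_ratio = nScaffolds / nChromosomes,
    # composed from the per-category rates so the decomposition
    # R_error = R_translocation + R_inversion is exact in floating point
    r_error = rT + rI,
    r_translocation = rT,
    r_inversion = rI,
    r_translocation_uncorrected = sumT / lgUncorrected,
    r_inversion_uncorrected = sumI / lgUncorrected,
    anchor_rate = lContig / lgUncorrected * 100,
    n_scaffolds = nScaffolds,
    n_chromosomes = nChromosomes,
    denominator_corrected = lgCorrected,
    denominator_uncorrected = lgUncorrected,
    l_contig = lContig
  )
}

#' GC content of a sequence set
#'
#' Computed over unambiguous A/C/G/T bases only.
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @return GC fraction.
#' @export
gcContent <- function(seqs) {
  f <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
  acgt <- f[c("A", "C", "G", "T")]
  unname((acgt["G"] + acgt["C"]) / sum(acgt))
}

#' Assemble report metrics
#'
#' Gathers the four report sections into a JSON-serializable list:
#' summary (contiguity, counts, GC, ratios), adjusting result (heatmap
#' references), error adjustment (per-category exhibits, at most five
#' each), and additional information (per-iteration error counts,
#' chromosome length proportions, uncorrected-denominator rates).
#'
#' @param scaffoldLengths lengths of the final scaffolds, bp.
#' @param nChromosomes chromosome count from assignment.
#' @param calls error-call data.frame (all iterations).
#' @param lgCorrected,lgUncorrected,lContig see [qualityRatios()].
#' @param gc GC fraction or `NA`.
#' @param perIteration per-iteration log data.frame (or `NULL`).
#' @param chromosomeLengths lengths incl. leftover for the proportion
#'   chart (or `NULL`).
#' @param maxExhibits exhibits kept per category (five, per the report
#'   layout; all when fewer).
#' @return a named list with `schema` version.
#' @export
reportMetrics <- function(scaffoldLengths, nChromosomes, calls,
                          lgCorrected, lgUncorrected = lgCorrected,
                          lContig = lgUncorrected, gc = NA,
                          perIteration = NULL,
                          chromosomeLengths = NULL, maxExhibits = 5L) {
  errs <- calls[calls$category %in% c("translocation", "inversion"), ,
                drop = FALSE]
  ratios <- qualityRatios(
    nScaffolds = length(scaffoldLengths), nChromosomes = nChromosomes,
    transLengths = with(errs, (x_end - x_start)[category == "translocation"]),
    invLengths = with(errs, (x_end - x_start)[category == "inversion"]),
    lgCorrected = lgCorrected, lgUncorrected = lgUncorrected,
    lContig = lContig)
  exhibits <- lapply(
    stats::setNames(nm = c("translocation", "inversion", "debris")),
    function(cat_) {
      sub <- calls[calls$category == cat_, , drop = FALSE]
      sub <- sub[order(-(sub$x_end - sub$x_start)), , drop = FALSE]
      utils::head(sub[, c("iteration", "category", "x_start", "x_end",
                          "resolution", "score", "status")], maxExhibits)
    })
  props <- if (!is.null(chromosomeLengths))
    as.numeric(chromosomeLengths) / sum(chromosomeLengths) else numeric()
  list(
    schema = "hicCurator-report/1",
    summary = c(list(total_length = sum(scaffoldLengths),
                     gc = gc,
                     contiguity = contiguityStats(scaffoldLengths)),
                ratios),
    adjusting_result = list(pre_image = NA, post_image = NA),
    error_adjustment = exhibits,
    additional_information = list(
      per_iteration = perIteration,
      chromosome_length_proportions = props,
      error_counts = as.list(countByType(calls)))
  )
}

#' Write / read report JSON
#'
#' The JSON schema is versioned; `reportFromJson(reportToJson(x))`
#' recovers the metrics list.
#'
#' @param metrics a [reportMetrics()] list.
#' @param path output `.json` path.
#' @return `reportToJson`: `path` invisibly; `reportFromJson`: the
#'   metrics list.
#' @export
reportToJson <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' @rdname reportToJson
#' @export
reportFromJson <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in intersect(names(out), "summary"))
    if (is.list(out[[k]]$contiguity))
      out[[k]]$contiguity <- as.data.frame(out[[k]]$contiguity)
  out
}

htmlSection <- function(title, body) {
  sprintf("<section><h2>%s</h2>\n%s\n</section>", title, body)
}

htmlImage <- function(path, label) {
  if (is.null(path) || is.na(path) || !nzchar(path) || !file.exists(path)) {
    warning("report image missing: ", label, "; rendered with placeholder")
    return(sprintf('<div class="placeholder">[%s unavailable]</div>', label))
  }
  sprintf('<figure><img src="%s" alt="%s"/><figcaption>%s</figcaption></figure>',
          path, label, label)
}

htmlTable <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return("<p><em>none</em></p>")
  hd <- paste(sprintf("<th>%s</th>", names(df)), collapse = "")
  rows <- apply(df, 1, function(r)
    paste0("<tr>", paste(sprintf("<td>%s</td>", r), collapse = ""), "</tr>"))
  sprintf("<table><tr>%s</tr>%s</table>", hd, paste(rows, collapse = "\n"))
}

#' Render the assembly report (JSON + HTML)
#'
#' Produces `<prefix>.json` (the metrics, versioned schema) and
#' `<prefix>.html` with the four report sections: summary, adjusting
#' result (pre/post global heatmaps), error adjustment (up to five
#' exhibits per category) and additional information (per-iteration
#' counts, chromosome length proportions). The HTML references only
#' local assets; missing images render as placeholders with a warning.
#'
#' @param metrics a [reportMetrics()] list.
#' @param prefix output path prefix.
#' @param preImage,postImage optional paths to global heatmap PNGs.
#' @return named character vector of the two output paths, invisibly.
#' @export
renderReport <- function(metrics, prefix, preImage = NULL,
                         postImage = NULL) {
  jsonPath <- paste0(prefix, ".json")
  htmlPath <- paste0(prefix, ".html")
  metrics$adjusting_result$pre_image <-
    if (is.null(preImage)) NA else preImage
  metrics$adjusting_result$post_image <-
    if (is.null(postImage)) NA else postImage
  reportToJson(metrics, jsonPath)
  s <- metrics$summary
  summaryTable <- data.frame(
    metric = c("Total length (bp)", "Scaffolds", "Chromosomes",
               "CC ratio", "R_error", "R_translocation", "R_inversion",
               "Anchor rate (%)", "GC"),
    value = c(s$total_length, s$n_scaffolds, s$n_chromosomes,
              signif(s$cc_ratio, 6), signif(s$r_error, 6),
              signif(s$r_translocation, 6), signif(s$r_inversion, 6),
              signif(s$anchor_rate, 6), signif(s$gc, 4)))
  sec1 <- htmlSection("Summary", paste(
    htmlTable(summaryTable), htmlTable(s$contiguity), sep = "\n"))
  sec2 <- htmlSection("Adjusting result", paste(
    htmlImage(preImage, "global contact map, before correction"),
    htmlImage(postImage, "global contact map, after correction"),
    sep = "\n"))
  exhibits <- metrics$error_adjustment
  sec3 <- htmlSection("Error adjustment", paste(
    vapply(names(exhibits), function(cat_)
      sprintf("<h3>%s</h3>\n%s", cat_, htmlTable(exhibits[[cat_]])), ""),
    collapse = "\n"))
  add <- metrics$additional_information
  props <- add$chromosome_length_proportions
  propHtml <- if (length(props)) htmlTable(data.frame(
    chromosome = seq_along(props), proportion = signif(props, 4)))
    else "<p><em>no chromosome proportions</em></p>"
  sec4 <- htmlSection("Additional information", paste(
    htmlTable(add$per_iteration), propHtml, sep = "\n"))
  html <- sprintf(
    "<!DOCTYPE html><html><head><meta charset='utf-8'/>%s%s</head><body>\n%s\n%s\n%s\n%s\n</body></html>",
    "<title>Assembly curation report</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 8px}.placeholder{border:1px dashed #999;padding:1em;color:#666}</style>",
    sec1, sec2, sec3, sec4)
  writeLines(html, htmlPath)
  invisible(c(json = jsonPath, html = htmlPath))
}
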