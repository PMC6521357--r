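#' @importFrom data.table fread fwrite data.table as.data.table setorder :=
NULL

MODEL_FORMAT_VERSION <- "1.0"

.contextMatches <- function(context, target) {
  if (target == "CH") context %in% c("CHG", "CHH") else context == target
}

#' Construct a Methylome from a site table
#'
#' @param df A data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{strand} (+/-), \code{context}, \code{mc}, \code{t}.
#' @param sampleId Sample name.
#' @param context Declared context of the table ("CG" or "CH", or a single
#'   non-CG context).
#' @return A \linkS4class{Methylome}, sorted by (chrom, pos).
#' @export
Methylome <- function(df, sampleId = "sample", context = "CG") {
  df <- as.data.frame(df)
  o <- order(df$chrom, df$pos)
  df <- df[o, , drop = FALSE]
  gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L), strand = df$strand)
  mcols(gr)$context <- as.character(df$context)
  mcols(gr)$mc <- as.integer(df$mc)
  mcols(gr)$t <- as.integer(df$t)
  new("Methylome", sites = gr, sampleId = sampleId, context = context)
}

#' Read an allc-style cytosine methylation table
#'
#' Reads a tab-delimited per-sample methylome with columns
#' \code{chrom, pos, strand, context, mc, t} (1-based positions; a header
#' line is auto-detected by a non-numeric \code{pos} field), filters it to
#' the requested sequence context and returns a sorted
#' \linkS4class{Methylome}. \code{context = "CH"} reads CHG and CHH jointly.
#'
#' Malformed rows (negative counts, \code{mc > t}, bad strand) raise an
#' error naming the offending line; an empty result after context filtering
#' is also an error.
#'
#' @param path Path to the TSV file.
#' @param context One of "CG", "CH", "CHG", "CHH".
#' @param sampleId Sample name; defaults to the file name without extension.
#' @return A \linkS4class{Methylome}.
#' @export
readMethylome <- function(path, context = c("CG", "CH", "CHG", "CHH"),
                          sampleId = NULL) {
  context <- match.arg(context)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty methylome file: ", path)
  f1 <- strsplit(first, "\t", fixed = TRUE)[[1]]
  hasHeader <- length(f1) >= 2L && is.na(suppressWarnings(as.numeric(f1[2])))
  dt <- fread(path, header = hasHeader, sep = "\t",
              col.names = c("chrom", "pos", "strand", "context", "mc", "t"),
              colClasses = list(character = c(1, 3, 4)))
  offset <- if (hasHeader) 1L else 0L
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("bad strand '%s' at line %d of %s",
                 dt$strand[bad[1]], bad[1] + offset, path))
  bad <- which(is.na(dt$pos) | dt$pos < 1 | is.na(dt$mc) | is.na(dt$t) |
                 dt$mc < 0 | dt$t < 0 | dt$mc > dt$t)
  if (length(bad))
    stop(sprintf("malformed counts/position at line %d of %s (mc=%s, t=%s)",
                 bad[1] + offset, path, dt$mc[bad[1]], dt$t[bad[1]]))
  dt <- as.data.frame(dt)[.contextMatches(dt$context, context), ]
  if (!nrow(dt))
    stop("no ", context, "-context sites in ", path)
  Methylome(dt, sampleId = sampleId, context = context)
}

#' Combine Watson and Crick counts at CG dyads
#'
#' The CpG dinucleotide is symmetric: a Watson-strand cytosine at position
#' \code{i} and the Crick-strand cytosine at \code{i+1} interrogate the same
#' dyad. This pools their \code{mc} and \code{t} into a single record
#' anchored at the Watson position (strand \code{+}). Unpaired sites pass
#' through; a lone Crick site at position \code{j} is reported at \code{j-1}
#' under the same Watson-anchor convention. Total counts are conserved.
#'
#' @param m A CG-context \linkS4class{Methylome}.
#' @return A \linkS4class{Methylome} with all sites on the \code{+} strand.
#' @export
combineCGStrands <- function(m) {
  stopifnot(is(m, "Methylome"))
  if (m@context != "CG")
    stop("combineCGStrands requires a CG-context methylome, got ",
         m@context)
  gr <- m@sites
  if (!length(gr)) return(m)
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   pos = BiocGenerics::start(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   mc = mcols(gr)$mc, t = mcols(gr)$t)
  # anchor every record at its Watson position, then pool by position
  dt[, anchor := ifelse(strand == "-", pos - 1L, pos)]
  out <- dt[, list(mc = sum(mc), t = sum(t)), by = c("chrom", "anchor")]
  setorder(out, chrom, anchor)
  Methylome(data.frame(chrom = out$chrom, pos = out$anchor, strand = "+",
                       context = "CG", mc = out$mc, t = out$t),
            sampleId = m@sampleId, context = "CG")
}

#' Read / write labelled regions (BED4)
#'
#' Regions are exchanged as 4-column BED-like text: \code{chrom, start,
#' stop, label} with 0-based half-open coordinates; in memory they are a
#' \code{GRanges} (1-based) with a \code{label} metadata column.
#'
#' @param path File path.
#' @return \code{readRegions}: a sorted \code{GRanges} with \code{label}.
#' @export
readRegions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "stop", "label"))
  if (any(dt$start >= dt$stop)) stop("region with start >= stop in ", path)
  gr <- GRanges(dt$chrom, IRanges(dt$start + 1L, dt$stop))
  mcols(gr)$label <- dt$label
  BiocGenerics::sort(gr)
}

#' @param regions A \code{GRanges} with a \code{label} metadata column.
#' @rdname readRegions
#' @export
writeRegions <- function(regions, path) {
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = BiocGenerics::start(regions) - 1L,
                   stop = BiocGenerics::end(regions),
                   label = mcols(regions)$label)
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write / read called DMRs (BED6+)
#'
#' DMRs are written as BED6 plus extra columns: after \code{chrom, start,
#' stop, name, score, strand} come every metadata column of the input
#' (\code{nSites}, per-group mean levels, \code{meanAbsDiff},
#' \code{meanScore}, \code{direction}, and per-pair columns for time-series
#' calls). Coordinates are 0-based half-open; the BED score column is
#' \code{round(1000 * meanScore)}. A leading \code{#}-header records the
#' extra column names so that \code{readDmrs} round-trips the table.
#'
#' @param dmrs A sorted \code{GRanges} of called DMRs.
#' @param path Output path.
#' @export
writeDmrs <- function(dmrs, path) {
  extra <- as.data.frame(mcols(dmrs))
  header <- paste0("#chrom\tstart\tstop\tname\tscore\tstrand",
                   if (ncol(extra)) paste0("\t", paste(colnames(extra),
                                                       collapse = "\t")))
  writeLines(header, path)
  if (!length(dmrs)) return(invisible(path))
  score <- if ("meanScore" %in% colnames(extra))
    as.integer(pmin(1000, round(1000 * extra$meanScore))) else 0L
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(dmrs)),
                   start = BiocGenerics::start(dmrs) - 1L,
                   stop = BiocGenerics::end(dmrs),
                   name = sprintf("DMR_%d", seq_along(dmrs)),
                   score = score, strand = ".")
  if (ncol(extra)) dt <- cbind(dt, as.data.table(extra))
  fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname writeDmrs
#' @return \code{readDmrs}: a \code{GRanges} with the extra columns as
#'   metadata.
#' @export
readDmrs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("missing DMR header line in ", path)
  cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(lines) < 2L) return(GRanges())
  dt <- fread(path, header = FALSE, sep = "\t", skip = 1L, col.names = cols,
              colClasses = list(character = 1))
  gr <- GRanges(dt$chrom, IRanges(dt$start + 1L, dt$stop))
  extra <- setdiff(cols, c("chrom", "start", "stop", "name", "score",
                           "strand"))
  for (cn in extra) mcols(gr)[[cn]] <- dt[[cn]]
  gr
}

#' Serialise / deserialise a trained model
#'
#' Models are stored as versioned JSON text (weights, intercept,
#' calibration, feature hyperparameters, context). Loading a file with a
#' different format version or missing fields is an error;
#' \code{loadModel(saveModel(m))} reproduces identical scores on any input.
#'
#' @param model A \linkS4class{TrainedModel}.
#' @param path File path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "TrainedModel"))
  p <- model@params
  obj <- list(format = "histDMR-model", version = model@version,
              context = model@context, weights = model@weights,
              intercept = model@intercept, calibA = model@calibA,
              calibB = model@calibB,
              params = list(w = p@w, d = p@d, bins = p@bins,
                            smoothSpan = p@smoothSpan))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("unreadable model file ", path,
                                           ": ", conditionMessage(e)))
  need <- c("format", "version", "context", "weights", "intercept",
            "calibA", "calibB", "params")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("model file ", path, " missing fields: ",
         paste(miss, collapse = ", "))
  if (!identical(obj$format, "histDMR-model"))
    stop("not a histDMR model file: ", path)
  if (!identical(obj$version, MODEL_FORMAT_VERSION))
    stop("model format version mismatch: file has ", obj$version,
         ", this build reads ", MODEL_FORMAT_VERSION)
  pm <- obj$params
  pmiss <- setdiff(c("w", "d", "bins", "smoothSpan"), names(pm))
  if (length(pmiss))
    stop("model file ", path, " missing params: ",
         paste(pmiss, collapse = ", "))
  params <- new("FeatureParams", w = as.integer(pm$w), d = as.numeric(pm$d),
                bins = as.integer(pm$bins),
                smoothSpan = as.integer(pm$smoothSpan))
  new("TrainedModel", weights = as.numeric(obj$weights),
      intercept = as.numeric(obj$intercept), calibA = as.numeric(obj$calibA),
      calibB = as.numeric(obj$calibB), params = params,
      context = obj$context, version = obj$version)
}
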