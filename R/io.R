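#' Read an OTU count table
#'
#' Reads a tab-separated OTU table (first column = row ids, header row,
#' \code{#}-prefixed comment lines ignored) or a BIOM file (via the
#' \pkg{biomformat} package, when installed).  Orientation is normalized
#' internally so that the returned \code{SummarizedExperiment} always has
#' OTUs as rows and a \code{"counts"} assay; square tables require an
#' explicit \code{orientation}.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"biom"}.
#' @param orientation layout of the file: \code{"samples_by_otus"} (rows
#'   are samples) or \code{"otus_by_samples"}.
#' @return a \code{SummarizedExperiment}; empty OTUs or samples are
#'   reported with a message.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tOTU1\tOTU2", "S1\t3\t0", "S2\t0\t2", "S3\t1\t1"), tf)
#' readOtuTable(tf)
#' @export
readOtuTable <- function(path, format = c("tsv", "biom"),
                         orientation = c("samples_by_otus",
                                         "otus_by_samples")) {
    format <- match.arg(format)
    if (format == "biom") {
        if (!requireNamespace("biomformat", quietly = TRUE))
            stop("the 'biomformat' package is required for BIOM input",
                 call. = FALSE)
        bm <- biomformat::read_biom(path)
        m <- as(biomformat::biom_data(bm), "matrix")  # OTUs x samples
        orientation <- "otus_by_samples"
    } else {
        df <- utils::read.table(path, header = TRUE, sep = "\t",
                                comment.char = "#", check.names = FALSE,
                                row.names = 1L)
        m <- as.matrix(df)
        if (nrow(m) == ncol(m) && missing(orientation))
            stop("square table: specify 'orientation' explicitly",
                 call. = FALSE)
        orientation <- match.arg(orientation)
        if (orientation == "samples_by_otus") m <- t(m)
    }
    if (!is.numeric(m) || anyNA(m))
        stop("OTU table must be entirely numeric", call. = FALSE)
    if (any(m < 0)) stop("negative counts in OTU table", call. = FALSE)
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
        stop("duplicate OTU or sample ids", call. = FALSE)
    emptyOtus <- sum(rowSums(m) == 0)
    emptySamples <- sum(colSums(m) == 0)
    if (emptyOtus) message(emptyOtus, " OTU(s) have all-zero counts")
    if (emptySamples) message(emptySamples, " sample(s) have all-zero counts")
    SummarizedExperiment(assays = list(counts = m))
}

#' Write an OTU count table as TSV
#'
#' @param x a \code{SummarizedExperiment} with a \code{"counts"} assay, or
#'   an OTU-by-sample matrix.
#' @param path output file path.
#' @param orientation layout to write (default samples-by-OTUs, the
#'   common deposition format).
#' @return \code{path}, invisibly.
#' @export
writeOtuTable <- function(x, path,
                          orientation = c("samples_by_otus",
                                          "otus_by_samples")) {
    orientation <- match.arg(orientation)
    m <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
    if (is.null(rownames(m))) rownames(m) <- paste0("OTU", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
    if (orientation == "samples_by_otus") m <- t(m)
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a long-format edge table (mask verdicts or edge scores) as TSV
#'
#' @param x a \code{\linkS4class{TestabilityMask}} or
#'   \code{\linkS4class{EdgeScores}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEdgeTable <- function(x, path) {
    utils::write.table(edgeTable(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Run manifest for reproducibility
#'
#' Assembles (and optionally writes as YAML) a manifest sufficient to
#' reproduce a run bit for bit with the same package version: command
#' name, full configuration including seeds, input file checksums, and a
#' timestamp.
#'
#' @param command character label of the command run.
#' @param config named list of all parameters, including seeds.
#' @param inputs character vector of input file paths (md5-checksummed).
#' @param path optional YAML output path.
#' @return the manifest list, invisibly if written.
#' @export
runManifest <- function(command, config, inputs = character(),
                        path = NULL) {
    manifest <- list(
        command = command,
        package = "AssocTestability",
        version = as.character(utils::packageVersion("AssocTestability")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        config = config,
        inputs = if (length(inputs))
            as.list(tools::md5sum(inputs)) else list())
    if (!is.null(path)) {
        yaml::write_yaml(manifest, path)
        return(invisible(manifest))
    }
    manifest
}
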