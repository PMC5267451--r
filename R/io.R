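## caller-output dialects ----------------------------------------------------

## SV type spellings seen in caller outputs; NA marks types that are parsed
## but excluded from the analysis (translocations).
.TYPE_MAP <- c(DEL = "DEL", D = "DEL",
               INS = "INS", I = "INS", SI = "INS", LI = "INS",
               INV = "INV",
               DUP = "DUP", TD = "DUP",
               CTX = NA, ITX = NA)

#' Caller-output dialects
#'
#' Describes how to pull SV records out of a caller's tabular output.  Three
#' dialects are built in:
#' \describe{
#'   \item{\code{generic_tsv}}{the package's frozen interchange format:
#'     \code{chrom start end svtype svlen support [sample] [genotype]},
#'     tab-separated, 1-based inclusive coordinates. This is also what
#'     \code{\link{writeCallerCalls}} emits.}
#'   \item{\code{breakdancer_like}}{paired-end-mapping style columns
#'     \code{chr1 pos1 orient1 chr2 pos2 orient2 type size score num_reads};
#'     coordinates 1-based.}
#'   \item{\code{pindel_like}}{split-read style columns
#'     \code{type size chrom start end support}; coordinates 1-based.}
#' }
#'
#' @param name one of \code{"generic_tsv"}, \code{"breakdancer_like"},
#'   \code{"pindel_like"}.
#' @return a \code{CallerDialect} list with the column map.
#' @export
callerDialect <- function(name = c("generic_tsv", "breakdancer_like",
                                   "pindel_like")) {
    name <- match.arg(name)
    cols <- switch(name,
        generic_tsv = c(chrom = 1L, start = 2L, end = 3L, svtype = 4L,
                        size = 5L, support = 6L, sample = 7L, genotype = 8L),
        breakdancer_like = c(chrom = 1L, start = 2L, end = 5L, svtype = 7L,
                             size = 8L, support = 10L),
        pindel_like = c(svtype = 1L, size = 2L, chrom = 3L, start = 4L,
                        end = 5L, support = 6L))
    structure(list(name = name, cols = cols, typeMap = .TYPE_MAP),
              class = "CallerDialect")
}

#' Read SV calls from a caller's tabular output
#'
#' Lines starting with \code{#} and blank lines are skipped.  SV type spellings
#' are normalised (\code{TD} to DUP, \code{D} to DEL, \code{SI}/\code{LI} to
#' INS); translocation records (\code{CTX}/\code{ITX}) and unrecognised types
#' are skipped with one summarising warning.  A malformed row (too few columns
#' or non-numeric coordinates) is an error naming the offending line.
#'
#' @param path path to the file.
#' @param dialect a \code{\link{callerDialect}} or its name.
#' @param sample sample id assigned to all records (unless the dialect carries
#'   a sample column).
#' @param label label of the returned set; defaults to the file name.
#' @return an \code{SVCallSet}.
#' @export
readCallerCalls <- function(path, dialect = "generic_tsv",
                            sample = "sample1", label = NULL) {
    if (is.character(dialect))
        dialect <- callerDialect(dialect)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (is.null(label))
        label <- basename(path)
    lines <- readLines(path)
    lineno <- seq_along(lines)
    keep <- !grepl("^\\s*(#|$)", lines)
    lines <- lines[keep]
    lineno <- lineno[keep]
    if (!length(lines))
        return(SVCallSet(GRanges(), label = label))
    fields <- strsplit(trimws(lines), "[\t ]+")
    cols <- dialect$cols
    required <- cols[names(cols) %in% c("chrom", "start", "end", "svtype",
                                        "size", "support")]
    bad <- which(lengths(fields) < max(required))
    if (length(bad))
        stop(sprintf("malformed row at line %d: expected >= %d columns, got %d",
                     lineno[bad[1]], max(required), lengths(fields)[bad[1]]))
    pull <- function(col) vapply(fields, `[`, character(1), cols[[col]])
    num <- function(col) {
        v <- suppressWarnings(as.numeric(pull(col)))
        badv <- which(is.na(v))
        if (length(badv))
            stop(sprintf("malformed row at line %d: non-numeric '%s' field",
                         lineno[badv[1]], col))
        v
    }
    chrom <- pull("chrom")
    start <- num("start")
    size <- num("size")
    support <- as.integer(num("support"))
    rawtype <- toupper(pull("svtype"))
    endpos <- if ("end" %in% names(cols)) num("end") else start + size - 1
    svtype <- unname(dialect$typeMap[rawtype])
    known <- rawtype %in% names(dialect$typeMap)
    drop <- !known | is.na(svtype)
    if (any(drop))
        warning(sprintf("skipped %d record(s) of unsupported SV type (%s)",
                        sum(drop),
                        paste(unique(rawtype[drop]), collapse = ", ")))
    if (all(drop))
        return(SVCallSet(GRanges(), label = label))
    idx <- which(!drop)
    chrom <- chrom[idx]; start <- start[idx]; endpos <- endpos[idx]
    svtype <- svtype[idx]; size <- size[idx]; support <- support[idx]
    fields <- fields[idx]
    ins <- svtype == "INS"
    endpos[ins] <- start[ins]
    svlen <- abs(size)
    sampleCol <- if ("sample" %in% names(cols)) {
        vapply(fields, function(f)
            if (length(f) >= cols[["sample"]]) f[[cols[["sample"]]]]
            else sample, character(1))
    } else rep(sample, length(idx))
    genoCol <- if ("genotype" %in% names(cols)) {
        g <- vapply(fields, function(f)
            if (length(f) >= cols[["genotype"]]) f[[cols[["genotype"]]]]
            else "UNKNOWN", character(1))
        ifelse(g %in% .GENOTYPES, g, "UNKNOWN")
    } else rep("UNKNOWN", length(idx))
    gr <- GRanges(chrom, IRanges(start, endpos))
    SVCallSet(gr, label = label, svtype = svtype,
              svlen = ifelse(ins, svlen, endpos - start + 1),
              support = support, sample = sampleCol,
              caller = dialect$name, genotype = genoCol)
}

#' Write SV calls in the generic interchange format
#'
#' Emits the \code{generic_tsv} dialect (see \code{\link{callerDialect}});
#' \code{readCallerCalls} on the result reproduces the records.
#'
#' @param x an \code{SVCallSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCallerCalls <- function(x, path) {
    stopifnot(is(x, "SVCallSet"))
    gr <- svCalls(x)
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr),
                     svtype = svType(x), svlen = svLength(x),
                     support = svSupport(x), sample = svSample(x),
                     genotype = svGenotype(x))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#chrom\tstart\tend\tsvtype\tsvlen\tsupport\tsample\tgenotype",
               con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

## region / genome / pedigree inputs ----------------------------------------

#' Read a BED file of named regions
#'
#' Standard BED semantics: 0-based half-open input coordinates, converted to
#' the 1-based closed convention used throughout the package.  An optional 4th
#' column provides region names; further columns are ignored.
#'
#' @param path path to a BED (3+ columns) file.
#' @return a \code{GRanges}, named when the file has a name column.
#' @export
readBedRegions <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path)
    lineno <- seq_along(lines)
    keep <- !grepl("^\\s*(#|track|browser|$)", lines)
    lines <- lines[keep]
    lineno <- lineno[keep]
    if (!length(lines))
        return(GRanges())
    fields <- strsplit(trimws(lines), "[\t ]+")
    bad <- which(lengths(fields) < 3L)
    if (length(bad))
        stop(sprintf("malformed BED row at line %d: fewer than 3 columns",
                     lineno[bad[1]]))
    chrom <- vapply(fields, `[`, character(1), 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
    badn <- which(is.na(start0) | is.na(end0))
    if (length(badn))
        stop(sprintf("malformed BED row at line %d: non-numeric coordinates",
                     lineno[badn[1]]))
    rev <- which(end0 < start0)
    if (length(rev))
        stop(sprintf("malformed BED row at line %d: end < start",
                     lineno[rev[1]]))
    gr <- GRanges(chrom, IRanges(start0 + 1, end0))
    nm <- vapply(fields, function(f)
        if (length(f) >= 4L && nzchar(f[[4L]]) && f[[4L]] != ".") f[[4L]]
        else NA_character_, character(1))
    if (any(!is.na(nm)))
        names(gr) <- nm
    gr
}

#' Read a genome description (chromosome name, length)
#'
#' @param path two-column TSV: chromosome name, length in bp.
#' @return a \code{\link[GenomeInfoDb]{Seqinfo}}.
#' @export
readGenomeTsv <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "length"),
                            colClasses = c("character", "numeric"),
                            comment.char = "#")
    Seqinfo(df$chrom, df$length)
}

#' Read a sire-son pedigree table
#'
#' @param path two-column TSV: son id, sire id.  Several sons may share one
#'   sire; a row listing an animal as its own sire is an error.
#' @return \code{data.frame} with columns \code{son}, \code{sire}.
#' @export
readPedigree <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path)
    lineno <- seq_along(lines)
    keep <- !grepl("^\\s*(#|$)", lines)
    lines <- lines[keep]
    lineno <- lineno[keep]
    if (!length(lines))
        return(data.frame(son = character(), sire = character()))
    fields <- strsplit(trimws(lines), "[\t ]+")
    bad <- which(lengths(fields) < 2L)
    if (length(bad))
        stop(sprintf("malformed pedigree row at line %d", lineno[bad[1]]))
    son <- vapply(fields, `[`, character(1), 1L)
    sire <- vapply(fields, `[`, character(1), 2L)
    self <- which(son == sire)
    if (length(self))
        stop(sprintf("self-parenting pedigree row at line %d ('%s')",
                     lineno[self[1]], son[self[1]]))
    data.frame(son = son, sire = sire)
}

## VCF output ---------------------------------------------------------------

#' Write an SV call set as VCF 4.2 with symbolic alleles
#'
#' Records are written with symbolic ALTs \code{<DEL>}, \code{<INS>},
#' \code{<INV>}, \code{<DUP>} and the INFO keys \code{SVTYPE}, \code{END},
#' \code{SVLEN} (negative for deletions), \code{SUPPORT} and \code{CALLER}.
#' Contig headers are taken from \code{genome}; a record on a chromosome not in
#' \code{genome} is an error.
#'
#' @param x an \code{SVCallSet}.
#' @param genome a \code{Seqinfo} or named vector of chromosome lengths.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSvVcf <- function(x, genome, path) {
    stopifnot(is(x, "SVCallSet"))
    gg <- .genomeRanges(genome)
    contigs <- as.character(seqnames(gg))
    lens <- end(gg)
    gr <- svCalls(x)
    chrom <- as.character(seqnames(gr))
    unknown <- setdiff(unique(chrom), contigs)
    if (length(unknown))
        stop("record(s) on chromosome(s) absent from genome: ",
             paste(unknown, collapse = ", "))
    ord <- order(match(chrom, contigs), start(gr), end(gr))
    gr <- gr[ord]
    chrom <- chrom[ord]
    tp <- mcols(gr)$svtype
    svlen <- mcols(gr)$svlen
    svlen <- ifelse(tp == "DEL", -svlen, svlen)
    endinfo <- ifelse(tp == "INS", start(gr), end(gr))
    hdr <- c("##fileformat=VCFv4.2",
             "##source=svconcord",
             sprintf("##contig=<ID=%s,length=%d>", contigs, as.integer(lens)),
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
             "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant (negative for deletions)\">",
             "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting read count\">",
             "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Originating caller or consensus label\">",
             sprintf("##ALT=<ID=%s,Description=\"%s\">",
                     c("DEL", "INS", "INV", "DUP"),
                     c("Deletion", "Insertion", "Inversion",
                       "Tandem duplication")),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO"), collapse = "\t"))
    body <- if (length(gr)) {
        sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d;SUPPORT=%d;CALLER=%s",
                chrom, start(gr),
                sprintf("sv%05d", seq_along(gr)),
                tp, tp, as.integer(endinfo), as.integer(round(svlen)),
                mcols(gr)$support, mcols(gr)$caller)
    } else character()
    writeLines(c(hdr, body), path)
    invisible(path)
}
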