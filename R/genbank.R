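# ---------------------------------------------------------------------------
# GenBank flat-file output and input for compiled genomes.
#
# The writer emits standard LOCUS / FEATURES / ORIGIN sections with the
# compiler's feature vocabulary (promoter, RBS, CDS, terminator, spacer);
# the regulatory model parameters and auxiliary sequences travel in a
# structured COMMENT block so that a written file parses back to the exact
# genome it came from. The reader understands files produced by this
# writer (or any file using the same vocabulary).
# ---------------------------------------------------------------------------

#' Write a compiled genome as a GenBank flat file
#'
#' @param cg A `compiled_genome` from [compile_gtrn()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(cg, path) {
  stopifnot(inherits(cg, "compiled_genome"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  n <- nchar(cg$sequence)
  wl <- function(...) writeLines(paste0(...), con)
  wl(sprintf("LOCUS       %-17s %d bp    DNA     linear   SYN", cg$name, n))
  wl("DEFINITION  refactored genome compiled from a transcriptional",
     "")
  wl("            regulatory network model.")
  meta_json <- jsonlite::toJSON(cg$meta, auto_unbox = TRUE, digits = I(17))
  wl("COMMENT     gtrnr-meta:", as.character(meta_json))
  wl("FEATURES             Location/Qualifiers")
  for (f in cg$features) {
    loc <- if (f$strand == "-")
      sprintf("complement(%d..%d)", f$start, f$end)
    else sprintf("%d..%d", f$start, f$end)
    ftype <- if (f$type == "spacer") "misc_feature" else f$type
    wl(sprintf("     %-15s %s", ftype, loc))
    if (f$type == "spacer")
      wl("                     /note=\"isolation_spacer\"")
    for (qn in names(f$qualifiers)) {
      qv <- f$qualifiers[[qn]]
      if (is.null(qv) || (length(qv) == 1L && is.na(qv))) next
      wl(sprintf("                     /%s=\"%s\"", qn,
                 paste(qv, collapse = ",")))
    }
  }
  wl("ORIGIN")
  for (i in seq(1L, n, by = 60L)) {
    chunk <- substr(cg$sequence, i, min(i + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    wl(sprintf("%9d %s", i, tolower(paste(groups, collapse = " "))))
  }
  wl("//")
  invisible(path)
}

#' Read a GenBank flat file written by [write_genbank()]
#'
#' @param path GenBank file path.
#' @return A `compiled_genome` record.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[[1L]]))
    stop("not a GenBank file: missing LOCUS line")
  if (!any(lines == "//"))
    stop("truncated GenBank file: missing // record terminator")
  name <- strsplit(sub("^LOCUS\\s+", "", lines[[1L]]), "\\s+")[[1L]][1L]

  meta <- NULL
  ci <- grep("^COMMENT     gtrnr-meta:", lines)
  if (length(ci))
    meta <- jsonlite::fromJSON(sub("^COMMENT     gtrnr-meta:", "",
                                   lines[[ci[1L]]]),
                               simplifyVector = FALSE)

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(fstart) || !length(ostart))
    stop("truncated GenBank file: missing FEATURES or ORIGIN section")
  fend <- ostart[1L] - 1L

  features <- list()
  cur <- NULL
  for (ln in lines[seq(fstart[1L] + 1L, fend)]) {
    if (grepl("^     \\S", ln)) {               # new feature
      if (!is.null(cur)) features[[length(features) + 1L]] <- cur
      toks <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(toks) < 2L) stop("malformed feature line: ", ln)
      loc <- toks[[2L]]
      strand <- if (grepl("^complement\\(", loc)) "-" else "+"
      nums <- as.integer(strsplit(gsub("[^0-9.]", "", loc), "\\.\\.")[[1L]])
      if (length(nums) != 2L || any(is.na(nums)))
        stop("unparseable feature location: ", loc)
      ftype <- toks[[1L]]
      if (ftype == "misc_feature") ftype <- "spacer"
      cur <- list(type = ftype, start = nums[[1L]], end = nums[[2L]],
                  strand = strand, qualifiers = list())
    } else if (grepl("^\\s+/", ln)) {           # qualifier
      m <- regmatches(ln, regexec("^\\s+/([^=]+)=\"(.*)\"\\s*$", ln))[[1L]]
      if (length(m) == 3L && m[[2L]] != "note") {
        val <- m[[3L]]
        if (grepl(",", val, fixed = TRUE)) val <- strsplit(val, ",")[[1L]]
        cur$qualifiers[[m[[2L]]]] <- val
      }
    }
  }
  if (!is.null(cur)) features[[length(features) + 1L]] <- cur

  endi <- which(lines == "//")[1L]
  seq_lines <- lines[seq(ostart[1L] + 1L, endi - 1L)]
  seqs <- gsub("[^acgtACGT]", "", sub("^\\s*[0-9]+", "", seq_lines))
  genome_seq <- toupper(paste(seqs, collapse = ""))
  declared <- suppressWarnings(
    as.integer(sub("^LOCUS\\s+\\S+\\s+(\\d+) bp.*$", "\\1", lines[[1L]])))
  if (!is.na(declared) && declared != nchar(genome_seq))
    stop("truncated GenBank file: LOCUS declares ", declared,
         " bp but ORIGIN holds ", nchar(genome_seq))

  structure(list(name = name, sequence = genome_seq, features = features,
                 meta = meta),
            class = "compiled_genome")
}

#' Write a compiled genome as single-record FASTA
#'
#' @param cg A `compiled_genome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(cg, path) {
  stopifnot(inherits(cg, "compiled_genome"))
  dna <- Biostrings::DNAStringSet(cg$sequence)
  names(dna) <- cg$name
  Biostrings::writeXStringSet(dna, filepath = path, width = 70L)
  invisible(path)
}
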