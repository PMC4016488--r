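# ---------------------------------------------------------------------------
# Tab-separated genome interchange, environment tables, and run manifests.
#
# A genome directory holds genes.tsv, promoters.tsv, beta.tsv, gamma.tsv,
# operons.tsv and sequences.fasta. Numeric columns are written with full
# double precision so that load(save(g)) reproduces g exactly.
# ---------------------------------------------------------------------------

.num_chr <- function(x) sprintf("%.17g", x)

.read_tsv <- function(path, required, name) {
  if (!file.exists(path)) stop("missing table: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = character())
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(name, ": missing column(s): ", paste(missing, collapse = ", "))
  df
}

.split_semi <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1L]]
}

#' Save a genome as TSV tables plus a parts FASTA
#'
#' Writes `genes.tsv`, `promoters.tsv`, `beta.tsv`, `gamma.tsv`,
#' `operons.tsv` (long format, one row per cistron) and `sequences.fasta`
#' into a directory.
#'
#' @param g A [gtrn()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_genome <- function(g, dir) {
  validate_gtrn(g)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, fname) {
    utils::write.table(df, file.path(dir, fname), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  genes_df <- do.call(rbind, lapply(g$genes, function(gn) {
    data.frame(id = gn$id, delta = .num_chr(gn$delta),
               categories = paste(gn$categories, collapse = ";"),
               functions = paste(gn$functions, collapse = ";"),
               strand = gn$strand, orf_seq_ref = gn$orf_seq_ref,
               native_rbs_ref = gn$native_rbs_ref,
               home_operon = ifelse(is.na(gn$home_operon), "",
                                    gn$home_operon),
               stringsAsFactors = FALSE)
  }))
  w(genes_df, "genes.tsv")

  prom_df <- do.call(rbind, lapply(names(g$promoters), function(pid) {
    p <- g$promoters[[pid]]
    data.frame(id = pid, alpha = .num_chr(p$alpha),
               constitutive = as.integer(p$is_constitutive),
               region_ref = ifelse(is.na(p$region_ref), "", p$region_ref),
               tandem_candidate = as.integer(pid %in% g$tandem_candidates),
               stringsAsFactors = FALSE)
  }))
  w(prom_df, "promoters.tsv")

  beta_rows <- list(); gamma_rows <- list()
  for (pid in names(g$promoters)) {
    p <- g$promoters[[pid]]
    for (tf in names(p$beta))
      beta_rows[[length(beta_rows) + 1L]] <-
        data.frame(promoter_id = pid, regulator_gene_id = tf,
                   beta = .num_chr(p$beta[[tf]]), stringsAsFactors = FALSE)
    for (f in names(p$gamma))
      gamma_rows[[length(gamma_rows) + 1L]] <-
        data.frame(promoter_id = pid, factor_id = f,
                   gamma = .num_chr(p$gamma[[f]]), stringsAsFactors = FALSE)
  }
  empty_beta <- data.frame(promoter_id = character(),
                           regulator_gene_id = character(),
                           beta = character(), stringsAsFactors = FALSE)
  empty_gamma <- data.frame(promoter_id = character(),
                            factor_id = character(),
                            gamma = character(), stringsAsFactors = FALSE)
  w(if (length(beta_rows)) do.call(rbind, beta_rows) else empty_beta,
    "beta.tsv")
  w(if (length(gamma_rows)) do.call(rbind, gamma_rows) else empty_gamma,
    "gamma.tsv")

  op_rows <- list()
  for (op in g$operons) {
    for (i in seq_along(op$genes))
      op_rows[[length(op_rows) + 1L]] <- data.frame(
        operon_id = op$id, rank = i, gene_id = op$genes[[i]],
        primary_promoter = op$primary_promoter,
        tandem_promoters = paste(op$tandem_promoters, collapse = ";"),
        terminator_ref = ifelse(is.na(op$terminator_ref), "",
                                op$terminator_ref),
        strand = op$strand,
        locus = ifelse(is.na(op$locus), "", .num_chr(op$locus)),
        stringsAsFactors = FALSE)
  }
  w(do.call(rbind, op_rows), "operons.tsv")

  if (length(g$sequence_store)) {
    dna <- Biostrings::DNAStringSet(unlist(g$sequence_store))
    Biostrings::writeXStringSet(dna, file.path(dir, "sequences.fasta"),
                                width = 70L)
  } else {
    file.create(file.path(dir, "sequences.fasta"))
  }
  invisible(dir)
}

#' Load a genome from a TSV/FASTA directory
#'
#' Inverse of [save_genome()], with strict schema validation: missing
#' columns, duplicate gene ids, dangling promoter or gene references and
#' empty operon rows are reported with their table and row.
#'
#' @param dir Directory written by [save_genome()] (or following its
#'   schema).
#' @return A [gtrn()] object.
#' @export
load_genome <- function(dir) {
  genes_df <- .read_tsv(file.path(dir, "genes.tsv"),
                        c("id", "delta", "categories", "functions", "strand"),
                        "genes.tsv")
  if (anyDuplicated(genes_df$id))
    stop("genes.tsv: duplicate gene id(s): ",
         paste(unique(genes_df$id[duplicated(genes_df$id)]), collapse = ", "))
  prom_df <- .read_tsv(file.path(dir, "promoters.tsv"),
                       c("id", "alpha"), "promoters.tsv")
  beta_df <- .read_tsv(file.path(dir, "beta.tsv"),
                       c("promoter_id", "regulator_gene_id", "beta"),
                       "beta.tsv")
  gamma_df <- .read_tsv(file.path(dir, "gamma.tsv"),
                        c("promoter_id", "factor_id", "gamma"), "gamma.tsv")
  op_df <- .read_tsv(file.path(dir, "operons.tsv"),
                     c("operon_id", "rank", "gene_id", "primary_promoter"),
                     "operons.tsv")

  bad <- setdiff(beta_df$promoter_id, prom_df$id)
  if (length(bad))
    stop("beta.tsv: unknown promoter id(s): ", paste(bad, collapse = ", "),
         " (row ", which(beta_df$promoter_id %in% bad)[1L], ")")
  bad <- setdiff(beta_df$regulator_gene_id, genes_df$id)
  if (length(bad))
    stop("beta.tsv: unknown regulator gene(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(gamma_df$promoter_id, prom_df$id)
  if (length(bad))
    stop("gamma.tsv: unknown promoter id(s): ", paste(bad, collapse = ", "))

  store <- character()
  fasta_path <- file.path(dir, "sequences.fasta")
  if (file.exists(fasta_path) && file.size(fasta_path) > 0) {
    dna <- Biostrings::readDNAStringSet(fasta_path)
    store <- stats::setNames(as.character(dna), names(dna))
  }

  promoters <- list()
  for (i in seq_len(nrow(prom_df))) {
    pid <- prom_df$id[i]
    b <- beta_df[beta_df$promoter_id == pid, , drop = FALSE]
    gm <- gamma_df[gamma_df$promoter_id == pid, , drop = FALSE]
    region <- if ("region_ref" %in% names(prom_df) &&
                  nzchar(prom_df$region_ref[i])) prom_df$region_ref[i]
              else NA_character_
    promoters[[pid]] <- regulatory_function(
      alpha = as.numeric(prom_df$alpha[i]),
      beta = stats::setNames(as.numeric(b$beta), b$regulator_gene_id),
      gamma = stats::setNames(as.numeric(gm$gamma), gm$factor_id),
      region_ref = region)
  }
  cands <- if ("tandem_candidate" %in% names(prom_df))
    prom_df$id[prom_df$tandem_candidate == "1"] else character()

  genes <- list()
  for (i in seq_len(nrow(genes_df))) {
    r <- genes_df[i, ]
    genes[[r$id]] <- gene(
      id = r$id, delta = as.numeric(r$delta),
      categories = .split_semi(r$categories),
      functions = .split_semi(r$functions), strand = r$strand,
      orf_seq_ref = if ("orf_seq_ref" %in% names(r) && nzchar(r$orf_seq_ref))
        r$orf_seq_ref else NA_character_,
      native_rbs_ref = if ("native_rbs_ref" %in% names(r) &&
                           nzchar(r$native_rbs_ref)) r$native_rbs_ref
        else NA_character_,
      home_operon = if ("home_operon" %in% names(r) && nzchar(r$home_operon))
        r$home_operon else NA_character_)
  }

  if (any(!nzchar(op_df$gene_id))) {
    stop("operons.tsv: empty gene_id at row ",
         which(!nzchar(op_df$gene_id))[1L])
  }
  bad <- setdiff(op_df$gene_id, genes_df$id)
  if (length(bad))
    stop("operons.tsv: unknown gene id(s): ", paste(bad, collapse = ", "),
         " (row ", which(op_df$gene_id %in% bad)[1L], ")")
  bad <- setdiff(op_df$primary_promoter, prom_df$id)
  if (length(bad))
    stop("operons.tsv: unknown promoter id(s): ", paste(bad, collapse = ", "))

  operons <- list()
  for (oid in unique(op_df$operon_id)) {
    rows <- op_df[op_df$operon_id == oid, , drop = FALSE]
    rows <- rows[order(as.integer(rows$rank)), , drop = FALSE]
    tand <- .split_semi(rows$tandem_promoters[1L])
    badp <- setdiff(tand, prom_df$id)
    if (length(badp))
      stop("operons.tsv: operon '", oid, "' references unknown tandem ",
           "promoter(s): ", paste(badp, collapse = ", "))
    operons[[oid]] <- operon(
      id = oid, genes = rows$gene_id,
      primary_promoter = rows$primary_promoter[1L],
      tandem_promoters = tand,
      terminator_ref = if ("terminator_ref" %in% names(rows) &&
                           nzchar(rows$terminator_ref[1L]))
        rows$terminator_ref[1L] else NA_character_,
      strand = if ("strand" %in% names(rows)) rows$strand[1L] else "+",
      locus = if ("locus" %in% names(rows) && nzchar(rows$locus[1L]))
        as.numeric(rows$locus[1L]) else NA_real_)
  }

  gtrn(genes, operons, promoters, tandem_candidates = cands,
       sequence_store = store)
}

#' Save environments as a TSV table
#'
#' Long format: one row per environment x factor with columns `env_id`,
#' `factor_id`, `v`, `v_opt`.
#'
#' @param envs List of [environment_state()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_environments <- function(envs, path) {
  if (inherits(envs, "gtrn_environment")) envs <- list(envs)
  rows <- list()
  for (j in seq_along(envs)) {
    e <- envs[[j]]
    eid <- if (is.na(e$id)) paste0("env", j) else e$id
    for (f in names(e$v_opt))
      rows[[length(rows) + 1L]] <- data.frame(
        env_id = eid, factor_id = f,
        v = .num_chr(if (f %in% names(e$v)) e$v[[f]] else e$v_opt[[f]]),
        v_opt = .num_chr(e$v_opt[[f]]), stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load environments from a TSV table
#'
#' @param path Table written by [save_environments()] (columns `env_id`,
#'   `factor_id`, `v`, `v_opt`).
#' @return List of [environment_state()] objects, in order of first
#'   appearance.
#' @export
load_environments <- function(path) {
  df <- .read_tsv(path, c("env_id", "factor_id", "v", "v_opt"),
                  basename(path))
  lapply(unique(df$env_id), function(eid) {
    rows <- df[df$env_id == eid, , drop = FALSE]
    if (anyDuplicated(rows$factor_id))
      stop(basename(path), ": duplicate factor in environment '", eid, "'")
    environment_state(
      v = stats::setNames(as.numeric(rows$v), rows$factor_id),
      v_opt = stats::setNames(as.numeric(rows$v_opt), rows$factor_id),
      id = eid)
  })
}

#' Build a run manifest
#'
#' Captures everything needed to re-execute a run: the configuration, the
#' master seed, md5 digests of the input files, the package version and a
#' timestamp.
#'
#' @param config Named list of run configuration values.
#' @param seed Master RNG seed.
#' @param inputs Character vector of input file paths to digest.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, inputs = character()) {
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs)
    stats::setNames(as.character(d), basename(names(d)))
  } else NULL
  structure(
    list(config = config, seed = as.integer(seed), input_digests = digests,
         package_version = as.character(utils::packageVersion("gtrnr")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
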