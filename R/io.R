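#' Read a two-column chrom.sizes file
#'
#' @param path Path to a tab-separated file `chrom<TAB>length`.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "size"),
                         colClasses = c("character", "numeric"))
  stats::setNames(d$size, d$chrom)
}

#' Write / read per-bin counts as TSV
#'
#' Plain `chrom start end count` tables (0-based half-open), the on-disk
#' exchange format for binned counts.
#'
#' @param track A [count_track()].
#' @param path Output path.
#' @return `write_counts_tsv` returns `path` invisibly; `read_counts_tsv`
#'   returns a [count_track()].
#' @export
write_counts_tsv <- function(track, path) {
  stopifnot(inherits(track, "count_track"))
  gr <- track_to_granges(track)
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1,
                  end = GenomicRanges::end(gr),
                  count = as.integer(gr$score))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @param chrom_sizes Optional named chromosome lengths; inferred from the
#'   last bin end per chromosome when omitted.
#' @param sample,role Metadata for the returned [count_track()].
#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, chrom_sizes = NULL, sample = "sample",
                            role = "antibody") {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(d)))
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  bin_size <- max(d$end - d$start)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(d$end, d$chrom, max)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes),
                                   names(chrom_sizes))
  }
  counts <- lapply(split(d, d$chrom), function(x) x$count)
  count_track(counts[order(names(counts))], bin_size, chrom_sizes,
              sample = sample, role = role)
}

#' Write / read a binned track as bedGraph
#'
#' Missing bins are omitted from the file and come back as `NA` when the
#' file is re-read onto its grid.
#'
#' @param track A [binned_track()].
#' @param path Output path (`.bedgraph`).
#' @return `write_bedgraph` returns `path` invisibly; `read_bedgraph`
#'   returns a [binned_track()].
#' @export
write_bedgraph <- function(track, path) {
  gr <- track_to_granges(track)
  gr <- gr[!is.na(gr$score)]
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' @param chrom_sizes Named chromosome lengths of the target grid.
#' @param bin_size Bin width in bp of the target grid.
#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, chrom_sizes, bin_size) {
  gr <- rtracklayer::import.bedGraph(path)
  out <- empty_track(chrom_sizes, bin_size)
  v <- track_values(out)
  nb <- n_bins(chrom_sizes, bin_size)
  offset <- stats::setNames(c(0, cumsum(nb))[seq_along(nb)], names(nb))
  ch <- as.character(GenomicRanges::seqnames(gr))
  keep <- ch %in% names(nb)
  bin0 <- floor((GenomicRanges::start(gr)[keep] - 1) / bin_size)
  v[offset[ch[keep]] + bin0 + 1] <- gr$score[keep]
  set_track_values(out, v)
}

#' Write / read a domain set as BED
#'
#' BED6 output: the name field carries `id|state`; the BED score field is
#' the domain score scaled by 1000 and clipped to `[0, 1000]` per BED
#' convention (exact scores belong in a companion TSV, see
#' [write_domain_scores_tsv()]).
#'
#' @param domains A [domain_set()].
#' @param path Output path (`.bed`).
#' @return `write_domains_bed` returns `path` invisibly; `read_domains_bed`
#'   returns a [domain_set()].
#' @export
write_domains_bed <- function(domains, path) {
  sc <- domains$score * 1000
  sc[is.na(sc)] <- 0
  gr <- GenomicRanges::GRanges(
    seqnames = domains$chrom,
    ranges = IRanges::IRanges(domains$start + 1, domains$end),
    name = paste(domains$id, domains$state, sep = "|"),
    score = pmin(pmax(sc, 0), 1000))
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname write_domains_bed
#' @export
read_domains_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  parts <- strsplit(gr$name, "|", fixed = TRUE)
  domain_set(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             state = vapply(parts, `[`, "", 2),
             id = vapply(parts, `[`, "", 1))
}

#' Exact domain scores as TSV
#'
#' @param domains A scored [domain_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_scores_tsv <- function(domains, path) {
  utils::write.table(
    data.frame(id = domains$id, chrom = domains$chrom,
               start = domains$start, end = domains$end,
               state = domains$state, score = domains$score),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read dyad positions as BED3
#'
#' Each dyad centre becomes a 1-bp interval `[pos, pos + 1)`.
#'
#' @param dyads A [dyad_set()].
#' @param path Output path (`.bed`).
#' @return `write_dyads_bed` returns `path` invisibly; `read_dyads_bed`
#'   returns a [dyad_set()].
#' @export
write_dyads_bed <- function(dyads, path) {
  ch <- rep(names(dyads$positions),
            vapply(dyads$positions, length, integer(1)))
  pos <- unlist(dyads$positions, use.names = FALSE)
  d <- data.frame(chrom = ch, start = pos, end = pos + 1)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dyads_bed
#' @export
read_dyads_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "start", "end"),
                         colClasses = c("character", "numeric", "numeric"))
  dyad_set(lapply(split(d$start, d$chrom), sort))
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A [simulation_config()].
#' @param path Output path (`.yaml`).
#' @return `write_config_yaml` returns `path` invisibly; `read_config_yaml`
#'   returns a [simulation_config()].
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  x <- unclass(config)
  x$perturbation <- unclass(x$perturbation)
  x$chrom_sizes <- as.list(x$chrom_sizes)
  x$spike_chrom_sizes <- as.list(x$spike_chrom_sizes)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$chrom_sizes <- unlist(x$chrom_sizes)
  x$spike_chrom_sizes <- unlist(x$spike_chrom_sizes)
  x$perturbation <- do.call(perturbation_spec, x$perturbation)
  do.call(simulation_config, x)
}
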