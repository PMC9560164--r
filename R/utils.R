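# Internal helpers ----------------------------------------------------------

# MD3/MD4 aggregate to "MD" wherever events are counted.
.aggEvent <- function(e) {
  out <- e
  out[out %in% c("MD3", "MD4")] <- "MD"
  out
}

.isDivision <- function(e) e %in% c("BD", "MD3", "MD4")

# Build a histogram (named numeric, names = interval values sorted
# numerically) from a vector of observed intervals.
.histFromValues <- function(values) {
  if (!length(values)) return(stats::setNames(numeric(0), character(0)))
  tb <- table(values)
  h <- as.numeric(tb)
  names(h) <- names(tb)
  h[order(as.numeric(names(h)))]
}

# Drop zero-mass bins and re-sort a histogram by interval.
.tidyHist <- function(h) {
  h <- h[h > 0]
  if (!length(h)) return(stats::setNames(numeric(0), character(0)))
  h[order(as.numeric(names(h)))]
}

# Largest-remainder apportionment of `total` integer units proportional to
# non-negative weights w; ties broken by position.
.largestRemainder <- function(w, total) {
  if (total <= 0 || sum(w) <= 0) return(integer(length(w)))
  q <- w / sum(w) * total
  fl <- floor(q)
  rem <- as.integer(round(total - sum(fl)))
  out <- as.integer(fl)
  if (rem > 0) {
    frac <- q - fl
    give <- order(-frac, seq_along(frac))[seq_len(rem)]
    out[give] <- out[give] + 1L
  }
  out
}

# Birth class of every record: ROOT, BD_CHILD, MD_CHILD or CF_PRODUCT,
# derived from the parent's end event.
.birthClasses <- function(rec) {
  key <- paste(rec$lineage_id, rec$cell_id)
  parentEvent <- rec$end_event[match(paste(rec$lineage_id, rec$parent_cell_id), key)]
  out <- rep("ROOT", nrow(rec))
  out[!is.na(parentEvent) & parentEvent == "BD"] <- "BD_CHILD"
  out[!is.na(parentEvent) & parentEvent %in% c("MD3", "MD4")] <- "MD_CHILD"
  out[!is.na(parentEvent) & parentEvent == "CF"] <- "CF_PRODUCT"
  out
}

# For CF products, the pre-fusion class ("BD" or "MD") of the fusing cells,
# taken from the recorded parent member's own birth class.
.preFusionClasses <- function(rec, birthClass = .birthClasses(rec)) {
  key <- paste(rec$lineage_id, rec$cell_id)
  parentClass <- birthClass[match(paste(rec$lineage_id, rec$parent_cell_id), key)]
  out <- rep(NA_character_, nrow(rec))
  cf <- birthClass == "CF_PRODUCT"
  out[cf] <- ifelse(parentClass[cf] == "MD_CHILD", "MD", "BD")
  out
}

# One row per fusion pair: indices of the two members, the "carrier" first
# (the member recorded as parent of the merged cell, falling back to the
# lower (lineage_id, cell_id)).
.fusionPairs <- function(rec) {
  cf <- which(rec$end_event == "CF")
  if (!length(cf)) {
    return(data.frame(carrier = integer(0), partner = integer(0)))
  }
  key <- paste(rec$lineage_id, rec$cell_id)
  partnerIdx <- match(paste(rec$fusion_partner_lineage[cf],
                            rec$fusion_partner_cell[cf]), key)
  seen <- character(0)
  carrier <- integer(0); partner <- integer(0)
  hasChild <- key %in% paste(rec$lineage_id, rec$parent_cell_id)
  for (j in seq_along(cf)) {
    i <- cf[j]; p <- partnerIdx[j]
    if (is.na(p)) next
    pk <- paste(min(i, p), max(i, p))
    if (pk %in% seen) next
    seen <- c(seen, pk)
    if (hasChild[p] && !hasChild[i]) {
      carrier <- c(carrier, p); partner <- c(partner, i)
    } else {
      carrier <- c(carrier, i); partner <- c(partner, p)
    }
  }
  data.frame(carrier = carrier, partner = partner)
}
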