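// Built-in deterministic read mapper.
//
// Semantics: a hit at (strand, contig, s) is the minimum edit distance between
// the (oriented) read and any prefix of the contig starting at 0-based s,
// within a diagonal band of half-width k (end-to-end in the read, free end in
// the text).  A read is mapped if the genome-wide minimum distance is <= k;
// n_best counts every start attaining that minimum, enumerated exhaustively.
//
// Two engines share the scoring routine but nothing else:
//   * seed: pigeonhole k+1 exact seeds against a w-mer index, verify candidates
//   * scan: brute-force verification of every start in the genome (test oracle)
//
// Both return the best-hit summary plus, optionally, every hit with distance
// <= k (used for paired-end concordance resolution and transcript projection).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int INF = 1 << 28;

static inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      default: c = 'N';
    }
  }
  return r;
}

// Banded start-anchored semi-global distance: read vs prefixes of text[s..].
// Returns min edit distance, or k+1 if it provably exceeds k.
static int banded_dist(const std::string& read, const std::string& text,
                       long s, int k, std::vector<int>& prev,
                       std::vector<int>& cur) {
  const int L = (int)read.size();
  const long tlen = (long)text.size();
  const int avail = (int)std::min((long)(L + k), tlen - s);
  if (avail < L - k) return k + 1;
  for (int j = 0; j <= std::min(k, avail); ++j) prev[j] = j;
  for (int i = 1; i <= L; ++i) {
    const int jlo = std::max(1, i - k), jhi = std::min(avail, i + k);
    int rowmin = INF;
    if (i - k <= 0) { cur[0] = i; rowmin = i; } else cur[jlo - 1] = INF;
    const char rc = read[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const int sub = prev[j - 1] + (rc == text[s + j - 1] ? 0 : 1);
      const int del = (j - 1 >= i - k) ? cur[j - 1] + 1 : INF;   // gap in read
      const int ins = (j <= i - 1 + k) ? prev[j] + 1 : INF;      // gap in text
      int v = sub < del ? sub : del;
      if (ins < v) v = ins;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (rowmin > k) return k + 1;
    std::swap(prev, cur);
  }
  int best = INF;
  for (int j = std::max(0, L - k); j <= std::min(avail, L + k); ++j)
    best = std::min(best, prev[j]);
  return best > k ? k + 1 : best;
}

struct Hit {
  int strand;   // 0 = '+', 1 = '-'
  int contig;   // 0-based
  long pos;     // 0-based start
  int dist;
  bool operator<(const Hit& o) const {
    if (strand != o.strand) return strand < o.strand;
    if (contig != o.contig) return contig < o.contig;
    return pos < o.pos;
  }
};

struct MapResult {
  bool mapped; int contig; long pos; long pos_max; int strand; int n_best;
  int dist;
};

// Best hits whose starts lie within 2k of each other are shift-equivalent
// alignments of one genomic location (a substitution re-expressed as a gap,
// or an indel re-expressed as a shifted start, moves the start by at most
// ~2k); they are merged into one reported location spanning [pos, pos_max].
// Genuinely duplicated loci sit far apart and stay distinct, so n_best
// counts locations, not alignments.
static MapResult summarize_hits(int k, std::vector<Hit>& hits) {
  MapResult r;
  int best_d = k + 1;
  for (size_t i = 0; i < hits.size(); ++i) best_d = std::min(best_d, hits[i].dist);
  if (best_d > k) {
    r.mapped = false; r.contig = NA_INTEGER; r.pos = NA_INTEGER;
    r.pos_max = NA_INTEGER; r.strand = NA_INTEGER; r.n_best = 0;
    r.dist = NA_INTEGER;
    return r;
  }
  std::vector<Hit> best;
  for (size_t i = 0; i < hits.size(); ++i)
    if (hits[i].dist == best_d) best.push_back(hits[i]);
  std::sort(best.begin(), best.end());
  int n_clusters = 0;
  long first_pos = -1, first_max = -1;
  int first_contig = -1, first_strand = -1;
  for (size_t i = 0; i < best.size(); ++i) {
    const bool new_cluster = i == 0 ||
      best[i].strand != best[i - 1].strand ||
      best[i].contig != best[i - 1].contig ||
      best[i].pos - best[i - 1].pos > 2L * (long)k;
    if (new_cluster) {
      ++n_clusters;
      if (n_clusters == 1) {
        first_pos = best[i].pos;
        first_contig = best[i].contig;
        first_strand = best[i].strand;
      }
    }
    if (n_clusters == 1) first_max = best[i].pos;
  }
  r.mapped = true;
  r.contig = first_contig;
  r.pos = first_pos;
  r.pos_max = first_max;
  r.strand = first_strand;
  r.n_best = n_clusters;
  r.dist = best_d;
  return r;
}

static List pack_results(const std::vector<MapResult>& res,
                         const std::vector<int>& hit_read,
                         const std::vector<Hit>& all_hits, bool report_hits) {
  const int n = (int)res.size();
  LogicalVector mapped(n);
  IntegerVector contig(n), pos(n), pos_max(n), mapq(n), n_best(n), dist(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    mapped[i] = res[i].mapped;
    if (res[i].mapped) {
      contig[i] = res[i].contig + 1;
      pos[i] = (int)res[i].pos + 1;
      pos_max[i] = (int)res[i].pos_max + 1;
      strand[i] = res[i].strand == 0 ? "+" : "-";
      n_best[i] = res[i].n_best;
      dist[i] = res[i].dist;
      mapq[i] = res[i].n_best > 1 ? 0 : 37;
    } else {
      contig[i] = NA_INTEGER; pos[i] = NA_INTEGER; pos_max[i] = NA_INTEGER;
      strand[i] = NA_STRING; n_best[i] = 0; dist[i] = NA_INTEGER; mapq[i] = 0;
    }
  }
  DataFrame summary = DataFrame::create(
      _["mapped"] = mapped, _["contig_i"] = contig, _["pos"] = pos,
      _["pos_max"] = pos_max, _["strand"] = strand, _["mapq"] = mapq,
      _["n_best_hits"] = n_best, _["best_dist"] = dist);
  if (!report_hits) return List::create(_["summary"] = summary);
  const int m = (int)all_hits.size();
  IntegerVector hread(m), hcontig(m), hpos(m), hdist(m);
  CharacterVector hstrand(m);
  for (int i = 0; i < m; ++i) {
    hread[i] = hit_read[i] + 1;
    hcontig[i] = all_hits[i].contig + 1;
    hpos[i] = (int)all_hits[i].pos + 1;
    hdist[i] = all_hits[i].dist;
    hstrand[i] = all_hits[i].strand == 0 ? "+" : "-";
  }
  DataFrame hits = DataFrame::create(
      _["read"] = hread, _["strand"] = hstrand, _["contig_i"] = hcontig,
      _["pos"] = hpos, _["dist"] = hdist);
  return List::create(_["summary"] = summary, _["hits"] = hits);
}

// [[Rcpp::export(name = ".cpp_map_reads_seed")]]
List cpp_map_reads_seed(CharacterVector reads, CharacterVector genome,
                        int k, bool both_strands, bool report_hits) {
  std::vector<std::string> contigs(genome.size());
  for (int i = 0; i < genome.size(); ++i) contigs[i] = as<std::string>(genome[i]);
  const int nreads = reads.size();
  std::vector<MapResult> res(nreads);
  std::vector<int> hit_read;
  std::vector<Hit> all_hits;
  if (nreads == 0) return pack_results(res, hit_read, all_hits, report_hits);

  const int L = (int)strlen(CHAR(STRING_ELT(reads, 0)));
  int w = L / (k + 1);
  if (w > 16) w = 16;
  if (w < 4) stop("reads too short for seeded mapping with this k");

  // w-mer index over all contigs
  std::unordered_map<uint64_t, std::vector<uint64_t> > index;
  const uint64_t mask = (1ULL << (2 * w)) - 1;
  for (size_t c = 0; c < contigs.size(); ++c) {
    const std::string& t = contigs[c];
    uint64_t key = 0; int run = 0;
    for (long p = 0; p < (long)t.size(); ++p) {
      const int b = base2(t[p]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= w)
        index[key].push_back(((uint64_t)c << 40) | (uint64_t)(p - w + 1));
    }
  }

  std::vector<int> prev(L + k + 2), cur(L + k + 2);
  std::vector<std::pair<int, long> > cands;
  for (int r = 0; r < nreads; ++r) {
    const std::string seq = as<std::string>(reads[r]);
    if ((int)seq.size() != L) stop("all reads in one call must share a length");
    const std::string rseq = both_strands ? revcomp(seq) : std::string();
    std::vector<Hit> hits;
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      const std::string& q = strand == 0 ? seq : rseq;
      cands.clear();
      for (int piece = 0; piece <= k; ++piece) {
        const int off = piece * w;
        uint64_t key = 0; bool ok = true;
        for (int j = 0; j < w; ++j) {
          const int b = base2(q[off + j]);
          if (b < 0) { ok = false; break; }
          key = (key << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          const uint64_t packed = it->second[h];
          const int c = (int)(packed >> 40);
          const long p = (long)(packed & ((1ULL << 40) - 1));
          const long s0 = p - off;
          for (long s = s0 - k; s <= s0 + k; ++s)
            if (s >= 0 && s < (long)contigs[c].size())
              cands.push_back(std::make_pair(c, s));
        }
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      for (size_t i = 0; i < cands.size(); ++i) {
        const int d = banded_dist(q, contigs[cands[i].first], cands[i].second,
                                  k, prev, cur);
        if (d <= k)
          hits.push_back(Hit{strand, cands[i].first, cands[i].second, d});
      }
    }
    res[r] = summarize_hits(k, hits);
    if (report_hits)
      for (size_t i = 0; i < hits.size(); ++i) {
        hit_read.push_back(r);
        all_hits.push_back(hits[i]);
      }
  }
  return pack_results(res, hit_read, all_hits, report_hits);
}

// [[Rcpp::export(name = ".cpp_map_reads_scan")]]
List cpp_map_reads_scan(CharacterVector reads, CharacterVector genome,
                        int k, bool both_strands, bool report_hits) {
  std::vector<std::string> contigs(genome.size());
  for (int i = 0; i < genome.size(); ++i) contigs[i] = as<std::string>(genome[i]);
  const int nreads = reads.size();
  std::vector<MapResult> res(nreads);
  std::vector<int> hit_read;
  std::vector<Hit> all_hits;
  for (int r = 0; r < nreads; ++r) {
    const std::string seq = as<std::string>(reads[r]);
    const int L = (int)seq.size();
    std::vector<int> prev(L + k + 2), cur(L + k + 2);
    const std::string rseq = both_strands ? revcomp(seq) : std::string();
    std::vector<Hit> hits;
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      const std::string& q = strand == 0 ? seq : rseq;
      for (size_t c = 0; c < contigs.size(); ++c) {
        const long clen = (long)contigs[c].size();
        for (long s = 0; s < clen; ++s) {
          const int d = banded_dist(q, contigs[c], s, k, prev, cur);
          if (d <= k) hits.push_back(Hit{strand, (int)c, s, d});
        }
      }
    }
    res[r] = summarize_hits(k, hits);
    if (report_hits)
      for (size_t i = 0; i < hits.size(); ++i) {
        hit_read.push_back(r);
        all_hits.push_back(hits[i]);
      }
  }
  return pack_results(res, hit_read, all_hits, report_hits);
}
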