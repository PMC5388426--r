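#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Seed-anchored ungapped aligner.
//
// The seed is the seed_len bases at the 3' end of the transcript-space read
// (the read suffix). Candidate placements are every genomic location, on
// either strand, where the seed matches with at most seed_mm substitutions;
// candidates are found exactly by the pigeonhole principle: the seed is cut
// into seed_mm + 1 parts, and any placement with <= seed_mm mismatches must
// match at least one part exactly. Each candidate is extended ungapped over
// the full read; placements are ranked by total mismatch count and, with
// unique_only, a tie in the best stratum rejects the read as multimapped.
// Any comparison involving an N (read or genome) counts as a mismatch.

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

struct PartIndex {
  int len;                  // part length
  int off;                  // offset of the part within the seed
  std::vector<int> starts;  // CSR offsets, size 4^len + 1
  std::vector<int> pos;     // seed-start positions (padded coordinates)
};

struct StrandIdx {
  std::string seq;  // padded sequence the index was built over
  int pad;          // left pad (circular wrap), 0 when linear
  int L;            // true contig length
  int contig;       // contig number (0-based)
  char strand;      // '+' aligns the read to the forward string,
                    // '-' to the reverse complement
  std::vector<PartIndex> parts;
};

static void build_parts(StrandIdx& si, int seed_len, int n_parts) {
  const std::string& s = si.seq;
  int n = (int) s.size();
  int n_starts = si.pad > 0 ? si.L : si.L - seed_len + 1;  // circular : linear
  if (n_starts < 0) n_starts = 0;

  // part lengths: as equal as possible
  std::vector<int> lens(n_parts, seed_len / n_parts);
  for (int j = 0; j < seed_len % n_parts; ++j) lens[j]++;

  int off = 0;
  for (int j = 0; j < n_parts; ++j) {
    PartIndex pi;
    pi.len = lens[j];
    pi.off = off;
    off += lens[j];
    int nbuckets = 1 << (2 * pi.len);

    // rolling codes of every window of length pi.len; -1 if it contains N
    std::vector<int> codes(n >= pi.len ? n - pi.len + 1 : 0, -1);
    int cur = 0, valid = 0, mask = nbuckets - 1;
    for (int i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; cur = 0; }
      else { cur = ((cur << 2) | c) & mask; valid++; }
      if (i >= pi.len - 1 && valid >= pi.len) codes[i - pi.len + 1] = cur;
    }

    std::vector<int> cnt(nbuckets + 1, 0);
    for (int sp = 0; sp < n_starts; ++sp) {
      int p = si.pad + sp + pi.off;
      if (p < (int) codes.size() && codes[p] >= 0) cnt[codes[p] + 1]++;
    }
    for (int b = 0; b < nbuckets; ++b) cnt[b + 1] += cnt[b];
    pi.starts = cnt;
    pi.pos.resize(cnt[nbuckets]);
    std::vector<int> fill(nbuckets, 0);
    for (int sp = 0; sp < n_starts; ++sp) {
      int p = si.pad + sp + pi.off;
      if (p < (int) codes.size() && codes[p] >= 0) {
        int b = codes[p];
        pi.pos[pi.starts[b] + fill[b]++] = si.pad + sp;
      }
    }
    si.parts.push_back(pi);
  }
}

// count mismatches between read[from..to) and seq[sp_read_start + from ...],
// early exit when count exceeds cap (returns cap + 1)
static inline int count_mm(const std::string& read, const std::string& seq,
                           int g0, int from, int to, int cap) {
  int mm = 0;
  for (int i = from; i < to; ++i) {
    char a = read[i], b = seq[g0 + i];
    if (a != b || a == 'N') {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
List cpp_align_reads(CharacterVector contig_seqs, CharacterVector reads,
                     int seed_len, int seed_mm, bool unique_only,
                     bool circular, int max_read_len) {
  int n_contigs = contig_seqs.size();
  int n_reads = reads.size();
  int n_parts = seed_mm + 1;

  std::vector<StrandIdx> idx;
  for (int c = 0; c < n_contigs; ++c) {
    std::string fwd = as<std::string>(contig_seqs[c]);
    int L = (int) fwd.size();
    if (L < seed_len) continue;
    for (int s = 0; s < 2; ++s) {
      StrandIdx si;
      si.contig = c;
      si.strand = s == 0 ? '+' : '-';
      si.L = L;
      std::string base = s == 0 ? fwd : revcomp(fwd);
      if (circular) {
        si.pad = max_read_len;
        si.seq = base.substr(L - std::min(si.pad, L)) + base +
                 base.substr(0, std::min(seed_len, L));
        if (si.pad > L) {  // wrap more than once not supported; pad with copies
          std::string left;
          while ((int) left.size() < si.pad) left = base + left;
          si.seq = left.substr(left.size() - si.pad) + base + base.substr(0, std::min(seed_len, L));
        }
      } else {
        si.pad = 0;
        si.seq = base;
      }
      build_parts(si, seed_len, n_parts);
      idx.push_back(si);
    }
  }

  IntegerVector status(n_reads);        // 0 aligned, 1 multimapped, 2 unaligned, 3 too_short
  IntegerVector contig(n_reads, NA_INTEGER);
  IntegerVector start(n_reads, NA_INTEGER);
  CharacterVector strand(n_reads, NA_STRING);
  IntegerVector n_mismatch(n_reads, NA_INTEGER);
  List offsets(n_reads);

  std::vector<int> cand;
  for (int r = 0; r < n_reads; ++r) {
    std::string read = as<std::string>(reads[r]);
    int rl = (int) read.size();
    if (rl < seed_len) { status[r] = 3; continue; }

    int best_mm = INT_MAX, best_count = 0;
    int best_idx = -1, best_sp = -1;

    for (size_t si_i = 0; si_i < idx.size(); ++si_i) {
      const StrandIdx& si = idx[si_i];
      if (rl > si.L && !circular) continue;
      cand.clear();
      // exact lookup of each seed part
      for (int j = 0; j < n_parts; ++j) {
        const PartIndex& pi = si.parts[j];
        int code = 0; bool ok = true;
        for (int i = 0; i < pi.len; ++i) {
          int c = base_code(read[rl - seed_len + pi.off + i]);
          if (c < 0) { ok = false; break; }
          code = (code << 2) | c;
        }
        if (!ok) continue;
        for (int q = pi.starts[code]; q < pi.starts[code + 1]; ++q)
          cand.push_back(pi.pos[q]);
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

      for (int sp : cand) {
        // sp = padded coordinate of the seed start
        int g0 = sp - (rl - seed_len);  // padded coordinate of the read start
        if (!circular) {
          if (g0 < 0 || sp + seed_len > si.L) continue;
        }
        int smm = count_mm(read, si.seq, g0, rl - seed_len, rl, seed_mm);
        if (smm > seed_mm) continue;
        int tmm = smm + count_mm(read, si.seq, g0, 0, rl - seed_len, INT_MAX - 1);
        if (tmm < best_mm) {
          best_mm = tmm; best_count = 1; best_idx = (int) si_i; best_sp = sp;
        } else if (tmm == best_mm) {
          best_count++;
        }
      }
    }

    if (best_count == 0) { status[r] = 2; continue; }
    if (unique_only && best_count > 1) { status[r] = 1; continue; }

    const StrandIdx& si = idx[best_idx];
    int g0 = best_sp - (rl - seed_len);
    // genomic leftmost (forward strand) 0-based start
    int gstart;
    if (si.strand == '+') {
      gstart = g0 - si.pad;
    } else {
      int r0 = g0 - si.pad;  // read start in revcomp coordinates
      gstart = si.L - (((r0 % si.L) + si.L) % si.L) - rl;
    }
    gstart = ((gstart % si.L) + si.L) % si.L;

    std::vector<int> offs;
    for (int i = 0; i < rl; ++i) {
      char a = read[i], b = si.seq[g0 + i];
      if (a != b || a == 'N') offs.push_back(i - (rl - 1));
    }
    status[r] = 0;
    contig[r] = si.contig + 1;
    start[r] = gstart;
    strand[r] = si.strand == '+' ? "+" : "-";
    n_mismatch[r] = best_mm;
    offsets[r] = wrap(offs);
  }

  return List::create(_["status"] = status, _["contig"] = contig,
                      _["start"] = start, _["strand"] = strand,
                      _["n_mismatch"] = n_mismatch, _["offsets"] = offsets);
}
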