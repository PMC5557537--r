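// Minimal seed-and-extend read aligner used as the package's built-in
// test surface. Exact k-mer seeds vote for candidate diagonals; candidates
// are rescored with a banded, affine-gap, glocal (read-global) alignment.
// One best alignment is reported per read, with the best score found at a
// locus more than one read length away kept as the "second best" feature.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // ambiguous
  }
}

static const char CODE2BASE[5] = {'A', 'C', 'G', 'T', 'N'};

struct Candidate {
  long long start;   // 0-based global start of the read on the forward genome
  int votes;
  bool rc;
};

struct Scored {
  int score;
  long long pos;     // 0-based global leftmost ref position of the alignment
  bool rc;
  int cand_index;
};

struct AlnResult {
  bool aligned = false;
  int contig = -1;       // 0-based contig index
  long long pos = 0;     // 0-based position within contig
  bool rc = false;
  int score = 0;
  bool has_second = false;
  int second = 0;
  int n_ties = 1;
  std::string cigar;
  std::string md;
};

// Banded glocal affine alignment of read (rows) against window (cols):
// read must be fully aligned, window prefix/suffix are free. Returns best
// score; fills cigar/md via traceback when requested.
struct BandedAligner {
  int match, mismatch, gap_open, gap_extend, band;
  // DP and traceback matrices, sized on demand
  std::vector<int> M, X, Y;       // X: gap in read (ref consumed), Y: gap in ref
  std::vector<uint8_t> tbM, tbX, tbY;
  int rows = 0, cols = 0;
  static constexpr int NEG = -1000000000;

  void resize(int L, int W) {
    rows = L + 1; cols = W + 1;
    size_t need = (size_t)rows * cols;
    if (M.size() < need) {
      M.assign(need, NEG); X.assign(need, NEG); Y.assign(need, NEG);
      tbM.assign(need, 0); tbX.assign(need, 0); tbY.assign(need, 0);
    }
  }
  inline size_t at(int i, int j) const { return (size_t)i * cols + j; }

  // read: codes[0..L), window: codes[0..W). Returns pair(score, start_col)
  // and, if tb, writes CIGAR (read-relative, forward direction) and MD.
  int align(const std::vector<int>& read, const int* win, int W,
            int* out_start, std::string* cigar, std::string* md) {
    int L = (int)read.size();
    resize(L, W);
    int b = band + std::max(0, W - L);  // widen to cover the whole window
    // column range for row i: [max(0,i-band), min(W, i + (W-L) + band)]
    auto lo = [&](int i) { return std::max(0, i - band); };
    auto hi = [&](int i) { return std::min(W, i + (W - L) + band); };
    (void)b;
    // row 0: free ref prefix
    for (int j = lo(0); j <= hi(0); ++j) {
      M[at(0, j)] = 0; X[at(0, j)] = NEG; Y[at(0, j)] = NEG;
      tbM[at(0, j)] = 0;
    }
    for (int i = 1; i <= L; ++i) {
      int jl = lo(i), jh = hi(i);
      for (int j = jl; j <= jh; ++j) {
        size_t c = at(i, j);
        // Y: gap in ref (consume read base i) from row i-1, same col
        int yM = NEG, yY = NEG;
        if (j >= lo(i - 1) && j <= hi(i - 1)) {
          yM = M[at(i - 1, j)] + gap_open + gap_extend;
          yY = Y[at(i - 1, j)] + gap_extend;
        }
        Y[c] = std::max(yM, yY);
        tbY[c] = (yY >= yM) ? 1 : 0;
        // X: gap in read (consume ref base j) from same row, col j-1
        int xM = NEG, xX = NEG;
        if (j - 1 >= jl) {
          xM = M[at(i, j - 1)] + gap_open + gap_extend;
          xX = X[at(i, j - 1)] + gap_extend;
        }
        X[c] = std::max(xM, xX);
        tbX[c] = (xX >= xM) ? 1 : 0;
        // M: diagonal
        int mm = NEG;
        uint8_t tb = 0;
        if (j >= 1 && j - 1 >= lo(i - 1) && j - 1 <= hi(i - 1)) {
          size_t d = at(i - 1, j - 1);
          int sub = (read[i - 1] < 4 && win[j - 1] < 4 &&
                     read[i - 1] == win[j - 1]) ? match : mismatch;
          int fromM = M[d], fromX = X[d], fromY = Y[d];
          int best = std::max(fromM, std::max(fromX, fromY));
          if (best > NEG / 2) {
            mm = best + sub;
            tb = (best == fromM) ? 0 : (best == fromX ? 1 : 2);
          }
        }
        M[c] = mm;
        tbM[c] = tb;
      }
    }
    // best over last row (free ref suffix), prefer smallest end col
    int best = NEG, bestj = -1;
    for (int j = lo(L); j <= hi(L); ++j) {
      int v = std::max(M[at(L, j)], X[at(L, j)]);  // X at end would be ref gap: not free, skip
      v = M[at(L, j)];
      if (v > best) { best = v; bestj = j; }
    }
    if (bestj < 0 || best <= NEG / 2) return NEG;
    if (out_start || cigar || md) {
      // traceback from (L, bestj) in state M
      std::vector<char> ops;          // 'M','I','D' per step, reversed
      std::vector<char> refbases;     // window bases consumed, reversed
      std::vector<bool> is_match;     // for M steps, reversed
      int i = L, j = bestj, state = 0;  // 0=M,1=X,2=Y
      while (i > 0) {
        size_t c = at(i, j);
        if (state == 0) {
          uint8_t tb = tbM[c];
          ops.push_back('M');
          refbases.push_back(CODE2BASE[win[j - 1]]);
          is_match.push_back(read[i - 1] < 4 && win[j - 1] < 4 &&
                             read[i - 1] == win[j - 1]);
          --i; --j; state = tb;
        } else if (state == 1) {  // X: ref gap (deletion from read's view)
          uint8_t tb = tbX[c];
          ops.push_back('D');
          refbases.push_back(CODE2BASE[win[j - 1]]);
          is_match.push_back(false);
          --j; state = tb ? 1 : 0;
        } else {  // Y: read gap (insertion)
          uint8_t tb = tbY[c];
          ops.push_back('I');
          refbases.push_back(0);
          is_match.push_back(false);
          --i; state = tb ? 2 : 0;
        }
      }
      if (out_start) *out_start = j;
      if (cigar) {
        std::string cg;
        int n = (int)ops.size();
        int run = 0; char cur = 0;
        for (int t = n - 1; t >= 0; --t) {
          if (ops[t] == cur) { ++run; }
          else {
            if (run) cg += std::to_string(run) + cur;
            cur = ops[t]; run = 1;
          }
        }
        if (run) cg += std::to_string(run) + cur;
        *cigar = cg;
      }
      if (md) {
        // MD over M/D ops, forward direction
        std::string m;
        int matchrun = 0;
        int n = (int)ops.size();
        bool lastWasDel = false;
        for (int t = n - 1; t >= 0; --t) {
          if (ops[t] == 'M') {
            if (is_match[t]) { ++matchrun; lastWasDel = false; }
            else {
              m += std::to_string(matchrun); matchrun = 0;
              m += refbases[t];
              lastWasDel = false;
            }
          } else if (ops[t] == 'D') {
            m += std::to_string(matchrun); matchrun = 0;
            if (!lastWasDel) m += '^';
            m += refbases[t];
            lastWasDel = true;
          } else {
            // I consumes no reference; force a 0 separator per MD convention
            if (lastWasDel) { lastWasDel = false; }
          }
        }
        m += std::to_string(matchrun);
        *md = m;
      }
    }
    return best;
  }
};

// [[Rcpp::export]]
List toy_align_cpp(CharacterVector contig_names, CharacterVector contig_seqs,
                   CharacterVector read_seqs,
                   int k, int match, int mismatch, int gap_open,
                   int gap_extend, double min_score_frac, int seed_stride,
                   int max_candidates, int band) {
  int ncontig = contig_names.size();
  {
    std::vector<std::string> nm;
    for (int i = 0; i < ncontig; ++i) nm.push_back(as<std::string>(contig_names[i]));
    std::sort(nm.begin(), nm.end());
    if (std::adjacent_find(nm.begin(), nm.end()) != nm.end())
      stop("duplicate contig names in reference");
  }
  // concatenated genome codes + contig offsets
  std::vector<long long> offset(ncontig + 1, 0);
  for (int i = 0; i < ncontig; ++i)
    offset[i + 1] = offset[i] + LENGTH(STRING_ELT(contig_seqs, i));
  long long G = offset[ncontig];
  std::vector<int> gcode((size_t)G);
  for (int i = 0; i < ncontig; ++i) {
    const char* s = CHAR(STRING_ELT(contig_seqs, i));
    long long len = offset[i + 1] - offset[i];
    for (long long p = 0; p < len; ++p) gcode[offset[i] + p] = base2code(s[p]);
  }
  // k-mer index over forward genome, within contigs only
  std::unordered_map<uint64_t, std::vector<uint32_t>> index;
  index.reserve((size_t)G);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int ci = 0; ci < ncontig; ++ci) {
    long long lo = offset[ci], hi = offset[ci + 1];
    uint64_t kmer = 0;
    int valid = 0;
    for (long long p = lo; p < hi; ++p) {
      int c = gcode[p];
      if (c >= 4) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        index[kmer].push_back((uint32_t)(p - k + 1));
      }
    }
  }

  int nreads = read_seqs.size();
  LogicalVector out_aligned(nreads);
  IntegerVector out_contig(nreads), out_pos(nreads), out_score(nreads),
      out_second(nreads), out_nties(nreads), out_mapq(nreads),
      out_alt(nreads);
  LogicalVector out_rc(nreads), out_has_second(nreads), out_has_alt(nreads);
  CharacterVector out_cigar(nreads), out_md(nreads);

  BandedAligner ba;
  ba.match = match; ba.mismatch = mismatch;
  ba.gap_open = gap_open; ba.gap_extend = gap_extend; ba.band = band;

  std::vector<Candidate> cands;
  std::unordered_map<long long, int> diag_votes;

  for (int r = 0; r < nreads; ++r) {
    const char* s = CHAR(STRING_ELT(read_seqs, r));
    int L = LENGTH(STRING_ELT(read_seqs, r));
    std::vector<int> fwd(L), rev(L);
    for (int i = 0; i < L; ++i) fwd[i] = base2code(s[i]);
    for (int i = 0; i < L; ++i) {
      int c = fwd[L - 1 - i];
      rev[i] = (c < 4) ? 3 - c : 4;
    }
    cands.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<int>& rd = (strand == 0) ? fwd : rev;
      if (L < k) break;
      diag_votes.clear();
      for (int off = 0; off + k <= L; off += seed_stride) {
        // also take the final seed flush with the read end
        int o = off;
        uint64_t kmer = 0;
        bool ok = true;
        for (int t = 0; t < k; ++t) {
          if (rd[o + t] >= 4) { ok = false; break; }
          kmer = ((kmer << 2) | (uint64_t)rd[o + t]) & mask;
        }
        if (!ok) continue;
        auto it = index.find(kmer);
        if (it == index.end()) continue;
        if (it->second.size() > 1024) continue;  // uninformative repeat seed
        for (uint32_t hp : it->second) {
          long long d = (long long)hp - o;
          diag_votes[d]++;
        }
      }
      for (auto& kv : diag_votes)
        cands.push_back({kv.first, kv.second, strand == 1});
    }
    if (cands.empty()) { out_aligned[r] = false; out_cigar[r] = "*"; continue; }
    // keep the most-voted candidates, deterministic order
    std::sort(cands.begin(), cands.end(), [](const Candidate& a, const Candidate& b) {
      if (a.votes != b.votes) return a.votes > b.votes;
      if (a.start != b.start) return a.start < b.start;
      return a.rc < b.rc;
    });
    if ((int)cands.size() > max_candidates) cands.resize(max_candidates);

    // gapless score on the exact seed diagonal; the banded DP is run only
    // when an indel-containing alignment could in principle score higher
    // (any gapped alignment scores at most match*L + gap_open + gap_extend)
    const int gap_bound = match * L + gap_open + gap_extend;
    struct Pre { int sg; long long start; bool rc; int ci; };
    std::vector<Pre> pres;
    for (int ci = 0; ci < (int)cands.size(); ++ci) {
      const Candidate& cd = cands[ci];
      int contig = (int)(std::upper_bound(offset.begin(), offset.end(), cd.start) -
                         offset.begin()) - 1;
      if (contig < 0 || contig >= ncontig) continue;
      long long clo = offset[contig], chi = offset[contig + 1];
      if (cd.start < clo || cd.start + L > chi) continue;
      const std::vector<int>& rd = cd.rc ? rev : fwd;
      int sg = 0;
      for (int i = 0; i < L; ++i) {
        int gb = gcode[cd.start + i];
        sg += (rd[i] < 4 && rd[i] == gb) ? match : mismatch;
      }
      pres.push_back({sg, cd.start, cd.rc, ci});
    }
    std::sort(pres.begin(), pres.end(), [](const Pre& a, const Pre& b) {
      if (a.sg != b.sg) return a.sg > b.sg;
      if (a.start != b.start) return a.start < b.start;
      return a.rc < b.rc;
    });
    std::vector<Scored> scored;
    int dp_done = 0;
    for (const Pre& pr : pres) {
      int sc = pr.sg;
      long long pos = pr.start;
      if (band > 0 && sc <= gap_bound && dp_done < 6) {
        ++dp_done;
        const Candidate& cd = cands[pr.ci];
        int contig = (int)(std::upper_bound(offset.begin(), offset.end(),
                                            cd.start) - offset.begin()) - 1;
        long long clo = offset[contig], chi = offset[contig + 1];
        long long wlo = std::max(clo, cd.start - band);
        long long whi = std::min(chi, cd.start + L + band);
        if (whi - wlo >= L) {
          const std::vector<int>& rd = cd.rc ? rev : fwd;
          int start_col = 0;
          int dp = ba.align(rd, &gcode[wlo], (int)(whi - wlo), &start_col,
                            nullptr, nullptr);
          if (dp > BandedAligner::NEG / 2 && dp > sc) {
            sc = dp;
            pos = wlo + start_col;
          }
        }
      }
      scored.push_back({sc, pos, pr.rc, pr.ci});
    }
    if (scored.empty()) { out_aligned[r] = false; out_cigar[r] = "*"; continue; }
    // best: highest score, ties by smallest position then forward strand
    std::sort(scored.begin(), scored.end(), [](const Scored& a, const Scored& b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.pos != b.pos) return a.pos < b.pos;
      return a.rc < b.rc;
    });
    const Scored& best = scored[0];
    int min_score = (int)(min_score_frac * (double)(match * L));
    if (best.score < min_score) { out_aligned[r] = false; out_cigar[r] = "*"; continue; }
    // second best at a distinct locus (> L away or other contig); also the
    // best alternative at ANY other position (reported as feature data
    // only, like an adapted aligner's suboptimal-score output — the native
    // MAPQ heuristic ignores it)
    bool has_second = false; int second = 0, nties = 1;
    bool has_alt = false; int alt = 0;
    for (size_t t = 1; t < scored.size(); ++t) {
      long long dist = scored[t].pos - best.pos;
      if (dist < 0) dist = -dist;
      if (dist > 0 && !has_alt) { has_alt = true; alt = scored[t].score; }
      if (dist > 0 && scored[t].score > alt) alt = scored[t].score;
      if (dist > L) {
        if (!has_second) { has_second = true; second = scored[t].score; }
        if (scored[t].score == best.score) ++nties;
      }
    }
    // recompute best with traceback for CIGAR/MD
    {
      const Candidate& cd = cands[best.cand_index];
      int contig = (int)(std::upper_bound(offset.begin(), offset.end(), cd.start) -
                         offset.begin()) - 1;
      long long clo = offset[contig], chi = offset[contig + 1];
      long long wlo = std::max(clo, cd.start - band);
      long long whi = std::min(chi, cd.start + L + band);
      const std::vector<int>& rd = cd.rc ? rev : fwd;
      int start_col = 0;
      std::string cigar, md;
      ba.align(rd, &gcode[wlo], (int)(whi - wlo), &start_col, &cigar, &md);
      out_aligned[r] = true;
      out_contig[r] = contig + 1;                        // 1-based for R
      out_pos[r] = (int)(wlo + start_col - clo + 1);     // 1-based in contig
      out_rc[r] = cd.rc;
      out_score[r] = best.score;
      out_has_second[r] = has_second;
      out_second[r] = second;
      out_has_alt[r] = has_alt;
      out_alt[r] = alt;
      out_nties[r] = nties;
      out_cigar[r] = cigar;
      out_md[r] = md;
      int mq;
      if (!has_second) mq = 40;
      else mq = std::min(40, 2 * (best.score - second));
      if (nties > 1) mq = 0;
      if (mq < 0) mq = 0;
      out_mapq[r] = mq;
    }
  }
  return List::create(
      _["aligned"] = out_aligned, _["contig"] = out_contig,
      _["pos"] = out_pos, _["rc"] = out_rc, _["score"] = out_score,
      _["has_second"] = out_has_second, _["second"] = out_second,
      _["has_alt"] = out_has_alt, _["alt"] = out_alt,
      _["n_ties"] = out_nties, _["cigar"] = out_cigar, _["md"] = out_md,
      _["mapq"] = out_mapq);
}
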