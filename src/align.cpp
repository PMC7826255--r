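// Compiled kernels for the amplicon pipeline: banded affine-gap global
// alignment with deterministic traceback, paired-end overlap merging,
// barcode demultiplexing and Hamming utilities.
//
// No RNG is used here; all randomness stays on the R side.

#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double NEG = -1e18;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (char& c : out) c = comp_base(c);
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    out[i] = revcomp_str(std::string(x[i]));
  }
  return out;
}

// Hamming distance of each sequence against a single reference of equal
// length; -1 where lengths differ.
// [[Rcpp::export]]
IntegerVector hamming_to_ref_cpp(CharacterVector seqs, std::string ref) {
  R_xlen_t n = seqs.size();
  IntegerVector out(n);
  size_t L = ref.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    if (std::strlen(s) != L) { out[i] = -1; continue; }
    int d = 0;
    for (size_t j = 0; j < L; ++j) if (s[j] != ref[j]) ++d;
    out[i] = d;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Banded global affine-gap alignment (Gotoh). ref consumed along i (rows),
// read along j (cols). Deletion = gap in the read (consumes ref); insertion =
// gap in the ref (consumes read). Traceback tie preference: diagonal, then
// deletion, then insertion (spec'd determinism; indels are left-normalised
// downstream anyway). Returns coalesced edit operations in reference
// coordinates (0-based, half-open) plus alignment summary statistics.
// ---------------------------------------------------------------------------

struct AlnResult {
  double score;
  int n_match, n_mismatch, n_cols;
  std::vector<int> kind;       // 1 = insertion, 2 = deletion
  std::vector<int> rstart, rend;
  std::vector<std::string> ins;
};

static bool align_banded(const std::string& ref, const std::string& read,
                         double match, double mismatch, double gap_open,
                         double gap_ext, int band, AlnResult& res) {
  const int n = (int)ref.size(), m = (int)read.size();
  const int dlo = std::min(0, n - m) - band;
  const int dhi = std::max(0, n - m) + band;
  const int W = dhi - dlo + 1;            // band width in diagonal units
  // index cell (i, j) with d = i - j in [dlo, dhi]: row j, offset d - dlo
  std::vector<double> M((size_t)(m + 1) * W, NEG), X((size_t)(m + 1) * W, NEG),
      Y((size_t)(m + 1) * W, NEG);
  auto idx = [&](int j, int d) { return (size_t)j * W + (size_t)(d - dlo); };
  auto inband = [&](int i, int j) {
    int d = i - j;
    return i >= 0 && i <= n && j >= 0 && j <= m && d >= dlo && d <= dhi;
  };
  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n && i <= dhi; ++i)
    X[idx(0, i)] = gap_open + gap_ext * i;
  for (int j = 1; j <= m && -j >= dlo; ++j)
    Y[idx(j, -j)] = gap_open + gap_ext * j;
  for (int j = 1; j <= m; ++j) {
    int ilo = std::max(1, j + dlo), ihi = std::min(n, j + dhi);
    for (int i = ilo; i <= ihi; ++i) {
      int d = i - j;
      // diagonal from (i-1, j-1): same d
      if (inband(i - 1, j - 1)) {
        double prev = std::max(M[idx(j - 1, d)],
                               std::max(X[idx(j - 1, d)], Y[idx(j - 1, d)]));
        if (prev > NEG / 2) {
          double s = (ref[i - 1] == read[j - 1]) ? match : mismatch;
          M[idx(j, d)] = prev + s;
        }
      }
      // deletion: from (i-1, j), d-1
      if (d - 1 >= dlo && inband(i - 1, j)) {
        double open = std::max(M[idx(j, d - 1)], Y[idx(j, d - 1)]) + gap_open + gap_ext;
        double ext = X[idx(j, d - 1)] + gap_ext;
        double v = std::max(open, ext);
        if (v > NEG / 2) X[idx(j, d)] = v;
      }
      // insertion: from (i, j-1), d+1
      if (d + 1 <= dhi && inband(i, j - 1)) {
        double open = std::max(M[idx(j - 1, d + 1)], X[idx(j - 1, d + 1)]) + gap_open + gap_ext;
        double ext = Y[idx(j - 1, d + 1)] + gap_ext;
        double v = std::max(open, ext);
        if (v > NEG / 2) Y[idx(j, d)] = v;
      }
    }
  }
  int dfin = n - m;
  if (dfin < dlo || dfin > dhi) return false;
  double sM = M[idx(m, dfin)], sX = X[idx(m, dfin)], sY = Y[idx(m, dfin)];
  double best = std::max(sM, std::max(sX, sY));
  if (best < NEG / 2) return false;
  res.score = best;
  // traceback, one alignment column per step; columns are coalesced into ops
  // afterwards. Per-column codes: 0 = diagonal, 1 = insertion, 2 = deletion.
  res.n_match = res.n_mismatch = res.n_cols = 0;
  int i = n, j = m;
  int state = (sM >= sX && sM >= sY) ? 0 : (sX >= sY ? 2 : 1);
  std::vector<int> colkind, coli, colj;  // collected 3'->5'
  const double eps = 1e-9;
  auto getM = [&](int ii, int jj) { return inband(ii, jj) ? M[idx(jj, ii - jj)] : NEG; };
  auto getX = [&](int ii, int jj) { return inband(ii, jj) ? X[idx(jj, ii - jj)] : NEG; };
  auto getY = [&](int ii, int jj) { return inband(ii, jj) ? Y[idx(jj, ii - jj)] : NEG; };
  while (i > 0 || j > 0) {
    ++res.n_cols;
    if (state == 0) {
      bool is_match = (ref[i - 1] == read[j - 1]);
      double s = is_match ? match : mismatch;
      if (is_match) ++res.n_match; else ++res.n_mismatch;
      double target = getM(i, j) - s;
      colkind.push_back(is_match ? 0 : 3); coli.push_back(i); colj.push_back(j);
      double pM = getM(i - 1, j - 1), pX = getX(i - 1, j - 1), pY = getY(i - 1, j - 1);
      --i; --j;
      if (pM >= target - eps) state = 0;
      else if (pX >= target - eps) state = 2;
      else if (pY >= target - eps) state = 1;
      else return false;  // inconsistent matrices (should not happen)
    } else if (state == 2) {  // deletion column, consumes ref[i-1]
      double cur = getX(i, j);
      colkind.push_back(2); coli.push_back(i); colj.push_back(j);
      double pX = getX(i - 1, j), pM = getM(i - 1, j), pY = getY(i - 1, j);
      --i;
      if (pX + gap_ext >= cur - eps) state = 2;  // prefer extending the run
      else if (pM + gap_open + gap_ext >= cur - eps) state = 0;
      else if (pY + gap_open + gap_ext >= cur - eps) state = 1;
      else return false;
    } else {  // insertion column, consumes read[j-1]
      double cur = getY(i, j);
      colkind.push_back(1); coli.push_back(i); colj.push_back(j);
      double pY = getY(i, j - 1), pM = getM(i, j - 1), pX = getX(i, j - 1);
      --j;
      if (pY + gap_ext >= cur - eps) state = 1;
      else if (pM + gap_open + gap_ext >= cur - eps) state = 0;
      else if (pX + gap_open + gap_ext >= cur - eps) state = 2;
      else return false;
    }
  }
  // coalesce adjacent same-kind columns (5'->3' order) into ops
  // (1 = insertion, 2 = deletion, 3 = substitution run with read bases)
  std::vector<int> kind, rstart, rend;
  std::vector<std::string> ins;
  for (int k = (int)colkind.size() - 1; k >= 0;) {
    if (colkind[k] == 0) { --k; continue; }
    int kk = colkind[k];
    int k2 = k;
    while (k2 - 1 >= 0 && colkind[k2 - 1] == kk) --k2;
    // columns k..k2 (reverse order) form one run; 5'->3' span:
    if (kk == 2) {
      kind.push_back(2);
      rstart.push_back(coli[k] - 1);   // leftmost column's ref base
      rend.push_back(coli[k2]);        // rightmost column's ref base + 1
      ins.push_back("");
    } else if (kk == 1) {
      std::string t;
      for (int q = k; q >= k2; --q) t += read[colj[q] - 1];
      kind.push_back(1);
      rstart.push_back(coli[k]);       // inter-base position after ref[i-1]
      rend.push_back(coli[k]);
      ins.push_back(t);
    } else {                           // substitution run: replacement bases
      std::string t;
      for (int q = k; q >= k2; --q) t += read[colj[q] - 1];
      kind.push_back(3);
      rstart.push_back(coli[k] - 1);
      rend.push_back(coli[k2]);
      ins.push_back(t);
    }
    k = k2 - 1;
  }
  res.kind = kind; res.rstart = rstart; res.rend = rend; res.ins = ins;
  return true;
}

// left-normalise an op list against the reference (shift indels into the
// leftmost equivalent placement), then merge ops that become adjacent
static void left_align_ops(const std::string& ref, std::vector<int>& kind,
                           std::vector<int>& rstart, std::vector<int>& rend,
                           std::vector<std::string>& ins) {
  for (size_t k = 0; k < kind.size(); ++k) {
    int lim = (k == 0) ? 0 : rend[k - 1];  // do not cross previous op
    if (kind[k] == 3) continue;            // substitutions do not slide
    if (kind[k] == 2) {
      int s = rstart[k], e = rend[k];
      while (s > lim && ref[s - 1] == ref[e - 1]) { --s; --e; }
      rstart[k] = s; rend[k] = e;
    } else {
      int p = rstart[k];
      std::string t = ins[k];
      size_t L = t.size();
      while (p > lim && L > 0 && ref[p - 1] == t[L - 1]) {
        t = t.substr(L - 1, 1) + t.substr(0, L - 1);
        --p;
      }
      rstart[k] = rend[k] = p;
      ins[k] = t;
    }
  }
}

// [[Rcpp::export]]
List align_one_cpp(std::string read, std::string ref, double match,
                   double mismatch, double gap_open, double gap_ext,
                   int band) {
  AlnResult res;
  bool ok = align_banded(ref, read, match, mismatch, gap_open, gap_ext, band, res);
  if (!ok) return List::create(_["ok"] = false);
  left_align_ops(ref, res.kind, res.rstart, res.rend, res.ins);
  return List::create(
      _["ok"] = true, _["score"] = res.score,
      _["n_match"] = res.n_match, _["n_mismatch"] = res.n_mismatch,
      _["n_cols"] = res.n_cols,
      _["kind"] = IntegerVector(res.kind.begin(), res.kind.end()),
      _["ref_start"] = IntegerVector(res.rstart.begin(), res.rstart.end()),
      _["ref_end"] = IntegerVector(res.rend.begin(), res.rend.end()),
      _["ins_seq"] = CharacterVector(res.ins.begin(), res.ins.end()));
}

// Vectorised caller used by the pipeline: aligns each unique read and emits a
// compact signature string "D:s-e;I:p:SEQ;..." (0-based, left-normalised,
// indels only), with identity and op bookkeeping. Substitutions are counted
// but never enter the signature. The exactly-matching read prefix and suffix
// (minus a safety margin wider than the band) are excluded from the DP and
// re-counted as matches; ops are shifted back to full-reference coordinates
// before left-normalisation against the full reference.
// [[Rcpp::export]]
List align_signatures_cpp(CharacterVector reads, std::string ref, double match,
                          double mismatch, double gap_open, double gap_ext,
                          int band_pad) {
  R_xlen_t n = reads.size();
  CharacterVector sig(n);
  NumericVector identity(n);
  IntegerVector n_indel(n);
  LogicalVector ok(n);
  const int nref = (int)ref.size();
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    const int nrd = (int)read.size();
    int band = band_pad + std::abs(nref - nrd);
    const int margin = band + 4;
    // exact common prefix / suffix, then retreat by `margin` so the DP band
    // still contains every optimal path
    int pre = 0;
    while (pre < nref && pre < nrd && ref[pre] == read[pre]) ++pre;
    pre = std::max(0, pre - margin);
    int suf = 0;
    while (suf < nref - pre && suf < nrd - pre &&
           ref[nref - 1 - suf] == read[nrd - 1 - suf]) ++suf;
    suf = std::max(0, suf - margin);
    std::string mref = ref.substr(pre, nref - pre - suf);
    std::string mread = read.substr(pre, nrd - pre - suf);
    AlnResult res;
    bool good = align_banded(mref, mread, match, mismatch, gap_open, gap_ext,
                             band, res);
    if (!good) { ok[r] = false; sig[r] = NA_STRING; identity[r] = 0.0; continue; }
    res.n_match += pre + suf;
    res.n_cols += pre + suf;
    for (size_t k = 0; k < res.kind.size(); ++k) {
      res.rstart[k] += pre;
      res.rend[k] += pre;
    }
    left_align_ops(ref, res.kind, res.rstart, res.rend, res.ins);
    std::string s;
    int nop = 0;
    for (size_t k = 0; k < res.kind.size(); ++k) {
      if (!s.empty()) s += ";";
      if (res.kind[k] == 2)
        s += "D:" + std::to_string(res.rstart[k]) + "-" + std::to_string(res.rend[k]);
      else
        s += "I:" + std::to_string(res.rstart[k]) + ":" + res.ins[k];
      ++nop;
    }
    ok[r] = true;
    sig[r] = s;
    n_indel[r] = nop;
    identity[r] = res.n_cols > 0 ? (double)res.n_match / res.n_cols : 0.0;
  }
  return List::create(_["ok"] = ok, _["signature"] = sig,
                      _["identity"] = identity, _["n_indel"] = n_indel);
}

// ---------------------------------------------------------------------------
// Paired-end overlap merging. r2 is reverse-complemented and slid along r1
// (offset o >= 0 of r2' start within r1 coordinates); among offsets with
// overlap >= min_overlap and mismatch fraction <= max_mismatch_frac the one
// maximising matched bases wins (ties: smallest offset, i.e. longest
// fragment). Overlap disagreements resolve toward the higher phred base;
// overlap quality is the per-base maximum.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector r1, CharacterVector r2, CharacterVector q1,
                     CharacterVector q2, int min_overlap,
                     double max_mismatch_frac) {
  R_xlen_t n = r1.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector ok(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    std::string a = as<std::string>(r1[t]);
    std::string b = revcomp_str(as<std::string>(r2[t]));
    std::string qa = as<std::string>(q1[t]);
    std::string qb = as<std::string>(q2[t]);
    std::reverse(qb.begin(), qb.end());
    int la = (int)a.size(), lb = (int)b.size();
    int best_matches = -1, best_o = -1;
    for (int o = 0; o <= la - min_overlap; ++o) {
      int hi = std::min(la, o + lb);
      int ov = hi - o;
      if (ov < min_overlap) break;
      int budget = (int)std::floor(max_mismatch_frac * ov);
      int mm = 0;
      for (int i = o; i < hi; ++i) {
        if (a[i] != b[i - o]) { if (++mm > budget) break; }
      }
      if (mm > budget) continue;
      int matches = ov - mm;
      if (matches > best_matches) { best_matches = matches; best_o = o; }
    }
    if (best_o < 0) { ok[t] = false; mseq[t] = NA_STRING; mqual[t] = NA_STRING; continue; }
    int o = best_o;
    int hi = std::min(la, o + lb);
    int mlen = std::max(la, o + lb);
    std::string s(mlen, 'N'), q(mlen, '!');
    for (int i = 0; i < o; ++i) { s[i] = a[i]; q[i] = qa[i]; }
    for (int i = o; i < hi; ++i) {
      char ca = a[i], cb = b[i - o];
      char qca = qa[i], qcb = qb[i - o];
      if (ca == cb) { s[i] = ca; }
      else { s[i] = (qca >= qcb) ? ca : cb; }
      q[i] = std::max(qca, qcb);
    }
    for (int i = hi; i < mlen; ++i) {
      if (i < la) { s[i] = a[i]; q[i] = qa[i]; }
      else { s[i] = b[i - o]; q[i] = qb[i - o]; }
    }
    ok[t] = true; mseq[t] = s; mqual[t] = q;
  }
  return List::create(_["ok"] = ok, _["seq"] = mseq, _["qual"] = mqual);
}

// Assign reads to barcodes by 5' prefix Hamming distance; 0 = unassigned
// (no barcode within max_mismatch, or tie between two barcodes).
// [[Rcpp::export]]
IntegerVector demux_assign_cpp(CharacterVector reads, CharacterVector barcodes,
                               int max_mismatch) {
  R_xlen_t n = reads.size(), nb = barcodes.size();
  std::vector<std::string> bc(nb);
  for (R_xlen_t k = 0; k < nb; ++k) bc[k] = as<std::string>(barcodes[k]);
  size_t blen = bc.empty() ? 0 : bc[0].size();
  IntegerVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    const char* s = CHAR(STRING_ELT(reads, t));
    if (std::strlen(s) < blen) { out[t] = 0; continue; }
    int best = INT_MAX, best_k = 0, nbest = 0;
    for (R_xlen_t k = 0; k < nb; ++k) {
      int d = 0;
      for (size_t j = 0; j < blen; ++j) if (s[j] != bc[k][j]) ++d;
      if (d < best) { best = d; best_k = (int)k + 1; nbest = 1; }
      else if (d == best) ++nbest;
    }
    out[t] = (best <= max_mismatch && nbest == 1) ? best_k : 0;
  }
  return out;
}
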