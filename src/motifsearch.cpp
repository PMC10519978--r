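// Hot kernels of the Motif-Search decoder: spacer k-mer-vote segmentation,
// CGK randomized embedding (edit -> Hamming), and affine-gap local alignment
// (ksw-style) of read windows against the motif library.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;  // ambiguity codes never vote
  }
}

// Spacer candidate positions by k-mer voting: every read k-mer matching a
// spacer k-mer at spacer offset o and read position p votes for normalized
// start p - o; positions below min_votes are dropped; surviving neighbours
// within merge_window collapse to a vote-weighted centroid.
// [[Rcpp::export]]
DataFrame C_spacer_candidates(std::string read, std::string spacer, int k,
                              int min_votes, int merge_window) {
  int n = (int)read.size(), m = (int)spacer.size();
  std::vector<int> pos_out, votes_out;
  if (n >= k && m >= k) {
    // 2-bit index of spacer k-mers -> offsets
    std::unordered_map<uint32_t, std::vector<int>> index;
    uint32_t code = 0, mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
    int valid = 0;
    for (int i = 0; i < m; ++i) {
      int b = base_code(spacer[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)b) & mask;
      if (++valid >= k) index[code].push_back(i - k + 1);
    }
    std::vector<int> votes(n, 0);
    code = 0; valid = 0;
    for (int p = 0; p < n; ++p) {
      int b = base_code(read[p]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)b) & mask;
      if (++valid >= k) {
        auto hit = index.find(code);
        if (hit != index.end()) {
          int kpos = p - k + 1;
          for (int off : hit->second) {
            int norm = kpos - off;
            if (norm >= 0) votes[norm]++;
          }
        }
      }
    }
    // threshold, then merge runs of near-neighbours to centroids
    std::vector<int> surv_pos, surv_votes;
    for (int i = 0; i < n; ++i)
      if (votes[i] >= min_votes) { surv_pos.push_back(i); surv_votes.push_back(votes[i]); }
    size_t i = 0;
    while (i < surv_pos.size()) {
      size_t j = i;
      double wsum = surv_votes[i], wpos = (double)surv_pos[i] * surv_votes[i];
      while (j + 1 < surv_pos.size() &&
             surv_pos[j + 1] - surv_pos[j] <= merge_window) {
        ++j;
        wsum += surv_votes[j];
        wpos += (double)surv_pos[j] * surv_votes[j];
      }
      pos_out.push_back((int)(wpos / wsum + 0.5));
      votes_out.push_back((int)wsum);
      i = j + 1;
    }
  }
  return DataFrame::create(Named("position") = pos_out,
                           Named("votes") = votes_out);
}

// CGK embedding of s (ACGT string) under one bit matrix (n_out x 4, 0/1):
// walk the string emitting the current character and advancing by the random
// bit for (output step, character); pad with 4 once the input is consumed.
static std::vector<uint8_t> cgk_embed(const std::string& s,
                                      const IntegerMatrix& bits) {
  int n_out = bits.nrow();
  std::vector<uint8_t> out((size_t)n_out, 4);
  int i = 0, n = (int)s.size();
  for (int j = 0; j < n_out && i < n; ++j) {
    int b = base_code(s[(size_t)i]);
    if (b < 0) b = 0;
    out[(size_t)j] = (uint8_t)b;
    i += bits(j, b);
  }
  return out;
}

// Mean Hamming distance between CGK embeddings of a and b over the supplied
// repetitions (list of shared bit matrices).
// [[Rcpp::export]]
double C_cgk_dist(std::string a, std::string b, List bit_mats) {
  double total = 0.0;
  int R = bit_mats.size();
  for (int r = 0; r < R; ++r) {
    IntegerMatrix bits = bit_mats[r];
    std::vector<uint8_t> ea = cgk_embed(a, bits), eb = cgk_embed(b, bits);
    int d = 0;
    for (size_t j = 0; j < ea.size(); ++j) d += (ea[j] != eb[j]);
    total += d;
  }
  return total / R;
}

// Smith-Waterman local alignment score with affine gaps (gap of length L
// costs gap_open + L * gap_ext), query vs each reference; returns the best
// local score per reference. Integer scores throughout.
// [[Rcpp::export]]
IntegerVector C_align_score_many(std::string query, CharacterVector refs,
                                 int match, int mismatch, int gap_open,
                                 int gap_ext) {
  int nq = (int)query.size();
  IntegerVector out(refs.size());
  std::vector<int> H(nq + 1), E(nq + 1);
  for (int ri = 0; ri < refs.size(); ++ri) {
    std::string ref = as<std::string>(refs[ri]);
    int nr = (int)ref.size();
    std::fill(H.begin(), H.end(), 0);
    std::fill(E.begin(), E.end(), 0);
    int best = 0;
    for (int i = 1; i <= nr; ++i) {
      int diag = 0, F = 0;
      char rc = ref[(size_t)(i - 1)];
      for (int j = 1; j <= nq; ++j) {
        int s = diag + (rc == query[(size_t)(j - 1)] ? match : mismatch);
        E[j] = std::max(E[j] - gap_ext, H[j] - gap_open - gap_ext);
        F = std::max(F - gap_ext, H[j - 1] - gap_open - gap_ext);
        int h = std::max(std::max(s, E[j]), std::max(F, 0));
        diag = H[j];
        H[j] = h;
        if (h > best) best = h;
      }
    }
    out[ri] = best;
  }
  return out;
}
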