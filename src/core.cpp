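// Core engine: entropy-based alignment objective, genetic-algorithm search,
// and the exhaustive brute-force oracle. Alignments are encoded as per-group
// binary gap masks over the columns of one or more frozen "blocks"; a block
// is a rows x columns grid of integer EC-token ids (0 = gap). Pairwise
// alignment uses two 1-row blocks; progressive profile extension uses a
// multi-row frozen block plus a 1-row block. All randomness comes from R's
// RNG so set.seed() on the R side makes every run reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

namespace {

struct Block {
  int nrow, ncol;
  std::vector<int> cells; // column-major, 0 = gap
  int at(int r, int c) const { return cells[c * nrow + r]; }
};

// Homogeneity lookup for the two-row case: cost[a * (T+1) + b] is the column
// homogeneity of the cell pair (a, b), 0 = gap. Both-gap columns are skipped
// by the caller. At S = 2 the row- and symbol-count entropy normalizations
// coincide (log2(2) = 1), so one table serves both modes.
struct PairTable {
  int T;
  std::vector<double> cost;
  double at(int a, int b) const { return cost[a * (T + 1) + b]; }
};

PairTable make_pair_table(const std::vector<int>& levels, int n_tokens,
                          double w1, double w2, double w3) {
  PairTable tab;
  tab.T = n_tokens;
  tab.cost.assign((size_t)(n_tokens + 1) * (n_tokens + 1), 0.0);
  double wsum = w1 + w2 + w3;
  for (int a = 0; a <= n_tokens; ++a) {
    for (int b = 0; b <= n_tokens; ++b) {
      double h;
      if (a == 0 && b == 0) h = 0.0;          // skipped anyway
      else if (a == 0 || b == 0) h = 1.0;     // EC vs gap: E = 1, gaps = 1
      else {
        double E = 0.0;
        if (levels[(a - 1) * 3 + 0] != levels[(b - 1) * 3 + 0]) E += w1;
        if (levels[(a - 1) * 3 + 1] != levels[(b - 1) * 3 + 1]) E += w2;
        if (levels[(a - 1) * 3 + 2] != levels[(b - 1) * 3 + 2]) E += w3;
        h = 0.6 * (E / wsum);
      }
      tab.cost[a * (tab.T + 1) + b] = h;
    }
  }
  return tab;
}

struct Problem {
  std::vector<Block> blocks;
  // levels[tok*3 + k] = integer id (>=1) of level k of token tok (tok >= 1)
  std::vector<int> levels;
  int n_tokens;
  int S;           // total number of rows
  int c0;          // longest original (ungapped) row length
  int max_level_id;
  double w1, w2, w3;            // EC-level entropy weights
  int gc_mode;                  // 0 literal, 1 inverted
  int ci_mode;                  // 0 literal, 1 inverted
  int norm_mode;                // 0: divide by log2(S); 1: by log2(#distinct)
  std::vector<double> plog;     // plog[c] = (c/S) * log2(c/S), c = 0..S
  double log2S;
  bool two_rows;                // fast path: S == 2 (both normalizations agree)
  PairTable pair_tab;
};

struct Chrom {
  std::vector<std::vector<unsigned char>> masks; // one per block, same length
  double fit, hom, gc, ci;
  bool evaluated;
  int width() const { return (int)masks[0].size(); }
};

// Remove positions where every group's mask is 0 (all-gap columns).
void normalize_masks(std::vector<std::vector<unsigned char>>& m) {
  const int G = (int)m.size();
  const int W = (int)m[0].size();
  int out = 0;
  for (int j = 0; j < W; ++j) {
    bool allzero = true;
    for (int g = 0; g < G; ++g)
      if (m[g][j]) { allzero = false; break; }
    if (!allzero) {
      if (out != j)
        for (int g = 0; g < G; ++g) m[g][out] = m[g][j];
      ++out;
    }
  }
  if (out != W)
    for (int g = 0; g < G; ++g) m[g].resize(out);
}

struct ScoreBuf {
  std::vector<int> cnt;      // counts per level id (0 = gap), reused
  std::vector<int> touched;
  std::vector<int> coltok;   // tokens of current column (0 = gap)
  std::vector<unsigned char> rowgap; // per-row gap pattern, row-major W per row
};


// Two-row fast path: column homogeneity from the pair table; gap runs
// tracked inline. Equivalent to the general path for S == 2.
void score_chrom_2row(const Problem& P, Chrom& ch) {
  const int G = (int)P.blocks.size();
  const int W = ch.width();
  int grp[2], rig[2];
  {
    int s = 0;
    for (int g = 0; g < G; ++g)
      for (int r = 0; r < P.blocks[g].nrow; ++r) { grp[s] = g; rig[s] = r; ++s; }
  }
  int cur[2] = {0, 0};
  double hom_sum = 0.0;
  int n_cols = 0;
  int run[2] = {0, 0}, run_start[2] = {-1, -1};
  long total_internal = 0;
  int n_blocks = 0;
  for (int j = 0; j < W; ++j) {
    int taken[2] = {-1, -1};
    for (int g = 0; g < G; ++g)
      if (ch.masks[g][j]) taken[g] = cur[g]++;
    int ta = (taken[grp[0]] >= 0) ? P.blocks[grp[0]].at(rig[0], taken[grp[0]]) : 0;
    int tb = (taken[grp[1]] >= 0) ? P.blocks[grp[1]].at(rig[1], taken[grp[1]]) : 0;
    if (ta == 0 && tb == 0) continue; // defensive: all-gap column
    hom_sum += P.pair_tab.at(ta, tb);
    int tok[2] = {ta, tb};
    for (int r = 0; r < 2; ++r) {
      if (tok[r] == 0) {
        if (run[r] == 0) run_start[r] = n_cols;
        ++run[r];
      } else if (run[r] > 0) {
        if (run_start[r] > 0) { total_internal += run[r]; ++n_blocks; }
        run[r] = 0;
      }
    }
    ++n_cols;
  }
  // open runs at the end of a row are trailing: ignored
  double hom = (n_cols > 0) ? hom_sum / n_cols : 0.0;
  double gc;
  if (total_internal == 0) gc = 0.0;
  else {
    double mean_block = (double)total_internal / (double)n_blocks;
    gc = (P.gc_mode == 0) ? mean_block / (double)total_internal
                          : (double)total_internal / (mean_block * (double)n_cols);
  }
  double ci = (n_cols > 0) ? (double)P.c0 / (double)n_cols : 1.0;
  if (P.ci_mode == 1) ci = 1.0 - ci;
  ch.hom = hom;
  ch.gc = gc;
  ch.ci = ci;
  ch.fit = 0.9 * hom + 0.05 * gc + 0.05 * ci;
  ch.evaluated = true;
}

// Score a chromosome. Assumes masks are normalized (no all-gap columns);
// columns that are nonetheless all-gap (defensive) are skipped.
void score_chrom(const Problem& P, Chrom& ch, ScoreBuf& buf) {
  if (P.two_rows) { score_chrom_2row(P, ch); return; }
  const int G = (int)P.blocks.size();
  const int W = ch.width();
  const int S = P.S;
  buf.cnt.assign(P.max_level_id + 1, 0);
  buf.coltok.resize(S);
  buf.rowgap.assign((size_t)S * W, 0);

  std::vector<int> cursor(G, 0);
  double hom_sum = 0.0;
  int n_cols = 0;

  for (int j = 0; j < W; ++j) {
    int sr = 0, n_gaps = 0;
    for (int g = 0; g < G; ++g) {
      const Block& B = P.blocks[g];
      if (ch.masks[g][j]) {
        int c = cursor[g]++;
        for (int r = 0; r < B.nrow; ++r) {
          int tok = B.at(r, c);
          buf.coltok[sr] = tok;
          if (tok == 0) { ++n_gaps; buf.rowgap[(size_t)(sr)*W + j] = 1; }
          ++sr;
        }
      } else {
        for (int r = 0; r < B.nrow; ++r) {
          buf.coltok[sr] = 0;
          ++n_gaps;
          buf.rowgap[(size_t)(sr)*W + j] = 1;
          ++sr;
        }
      }
    }
    if (n_gaps == S) continue; // defensive: all-gap column contributes nothing
    ++n_cols;

    double E = 0.0;
    const double wts[3] = {P.w1, P.w2, P.w3};
    double wsum = P.w1 + P.w2 + P.w3;
    for (int k = 0; k < 3; ++k) {
      buf.touched.clear();
      for (int s = 0; s < S; ++s) {
        int tok = buf.coltok[s];
        int id = (tok == 0) ? 0 : P.levels[(tok - 1) * 3 + k];
        if (buf.cnt[id] == 0) buf.touched.push_back(id);
        buf.cnt[id]++;
      }
      double H = 0.0;
      int distinct = (int)buf.touched.size();
      for (int id : buf.touched) { H -= P.plog[buf.cnt[id]]; buf.cnt[id] = 0; }
      double denom = (P.norm_mode == 0) ? P.log2S
                                        : (distinct > 1 ? std::log2((double)distinct) : 0.0);
      double Ek = (distinct <= 1 || denom <= 0.0) ? 0.0 : H / denom;
      if (Ek > 1.0) Ek = 1.0;
      E += wts[k] * Ek;
    }
    E /= wsum;
    double gapfrac = (double)n_gaps / (double)(S - 1);
    hom_sum += 0.6 * E + 0.4 * gapfrac;
  }

  double hom = (n_cols > 0) ? hom_sum / n_cols : 0.0;

  // gap concentration: internal gap runs per row (runs touching neither end)
  long total_internal = 0;
  int n_blocks = 0;
  for (int s = 0; s < S; ++s) {
    const unsigned char* row = &buf.rowgap[(size_t)s * W];
    int run = 0, start = -1;
    for (int j = 0; j <= W; ++j) {
      bool g = (j < W) ? row[j] != 0 : false;
      if (g) { if (run == 0) start = j; ++run; }
      else if (run > 0) {
        bool leading = (start == 0);
        bool trailing = (j == W); // run ended at row end
        if (!leading && !trailing) { total_internal += run; ++n_blocks; }
        run = 0;
      }
    }
  }
  double gc;
  if (total_internal == 0) gc = 0.0;
  else {
    double mean_block = (double)total_internal / (double)n_blocks;
    gc = (P.gc_mode == 0) ? mean_block / (double)total_internal
                          : (double)total_internal / (mean_block * (double)n_cols);
  }

  double ci = (n_cols > 0) ? (double)P.c0 / (double)n_cols : 1.0;
  if (P.ci_mode == 1) ci = 1.0 - ci;

  ch.hom = hom;
  ch.gc = gc;
  ch.ci = ci;
  ch.fit = 0.9 * hom + 0.05 * gc + 0.05 * ci;
  ch.evaluated = true;
}

Problem make_problem(List blocks_r, IntegerMatrix levels, double w1, double w2,
                     double w3, int gc_mode, int ci_mode, int norm_mode) {
  Problem P;
  P.n_tokens = levels.nrow();
  P.levels.resize((size_t)P.n_tokens * 3);
  P.max_level_id = 0;
  for (int t = 0; t < P.n_tokens; ++t)
    for (int k = 0; k < 3; ++k) {
      P.levels[t * 3 + k] = levels(t, k);
      if (levels(t, k) > P.max_level_id) P.max_level_id = levels(t, k);
    }
  P.S = 0;
  P.c0 = 0;
  for (int g = 0; g < blocks_r.size(); ++g) {
    IntegerMatrix m = blocks_r[g];
    Block B;
    B.nrow = m.nrow();
    B.ncol = m.ncol();
    B.cells.assign(m.begin(), m.end());
    // longest original row = max non-gap count per row
    for (int r = 0; r < B.nrow; ++r) {
      int n = 0;
      for (int c = 0; c < B.ncol; ++c)
        if (B.at(r, c) != 0) ++n;
      if (n > P.c0) P.c0 = n;
    }
    P.S += B.nrow;
    P.blocks.push_back(std::move(B));
  }
  P.w1 = w1; P.w2 = w2; P.w3 = w3;
  P.gc_mode = gc_mode; P.ci_mode = ci_mode; P.norm_mode = norm_mode;
  P.plog.resize(P.S + 1);
  P.plog[0] = 0.0;
  for (int c = 1; c <= P.S; ++c) {
    double p = (double)c / (double)P.S;
    P.plog[c] = p * std::log2(p);
  }
  P.log2S = std::log2((double)P.S);
  P.two_rows = (P.S == 2);
  if (P.two_rows) P.pair_tab = make_pair_table(P.levels, P.n_tokens, w1, w2, w3);
  return P;
}

int runif_int(int n) { // uniform on 0..n-1 via R's RNG
  int v = (int)std::floor(unif_rand() * n);
  if (v >= n) v = n - 1;
  return v;
}

Chrom random_chrom(const Problem& P, int max_extra) {
  const int G = (int)P.blocks.size();
  int Lmax = 0;
  for (auto& B : P.blocks) if (B.ncol > Lmax) Lmax = B.ncol;
  int W = Lmax + runif_int(max_extra + 1);
  Chrom ch;
  ch.evaluated = false;
  ch.masks.resize(G);
  std::vector<int> idx(W);
  for (int g = 0; g < G; ++g) {
    int w = P.blocks[g].ncol;
    ch.masks[g].assign(W, 0);
    for (int j = 0; j < W; ++j) idx[j] = j;
    // sample w positions for the 1s (partial Fisher-Yates)
    for (int t = 0; t < w; ++t) {
      int pick = t + runif_int(W - t);
      std::swap(idx[t], idx[pick]);
      ch.masks[g][idx[t]] = 1;
    }
  }
  normalize_masks(ch.masks);
  return ch;
}

Chrom trivial_chrom(const Problem& P) {
  const int G = (int)P.blocks.size();
  int Lmax = 0;
  for (auto& B : P.blocks) if (B.ncol > Lmax) Lmax = B.ncol;
  Chrom ch;
  ch.evaluated = false;
  ch.masks.resize(G);
  for (int g = 0; g < G; ++g) {
    int w = P.blocks[g].ncol;
    ch.masks[g].assign(Lmax, 0);
    for (int j = 0; j < w; ++j) ch.masks[g][j] = 1;
  }
  return ch;
}

// One-point crossover. cut is a column index in parent1, 1 <= cut < W1.
// Parent2's per-group cut point lies just after it has consumed as many
// non-gap symbols as parent1 holds left of the cut; shorter sides are padded
// with gap columns so each offspring stays rectangular.
void crossover_masks(const std::vector<std::vector<unsigned char>>& p1,
                     const std::vector<std::vector<unsigned char>>& p2,
                     int cut,
                     std::vector<std::vector<unsigned char>>& o1,
                     std::vector<std::vector<unsigned char>>& o2) {
  const int G = (int)p1.size();
  const int W2 = (int)p2[0].size();
  std::vector<int> d(G);
  for (int g = 0; g < G; ++g) {
    int nleft = 0;
    for (int j = 0; j < cut; ++j) nleft += p1[g][j];
    int seen = 0, pos = 0;
    while (seen < nleft && pos < W2) { seen += p2[g][pos]; ++pos; }
    d[g] = pos;
  }
  int Rmax = 0, Dmax = 0;
  for (int g = 0; g < G; ++g) {
    if (W2 - d[g] > Rmax) Rmax = W2 - d[g];
    if (d[g] > Dmax) Dmax = d[g];
  }
  o1.resize(G);
  o2.resize(G);
  const int W1 = (int)p1[0].size();
  for (int g = 0; g < G; ++g) {
    o1[g].clear();
    o2[g].clear();
    // offspring1 = left(p1) + [front pad] + right(p2)
    o1[g].reserve(cut + Rmax);
    o1[g].insert(o1[g].end(), p1[g].begin(), p1[g].begin() + cut);
    int pad = Rmax - (W2 - d[g]);
    o1[g].insert(o1[g].end(), pad, 0);
    o1[g].insert(o1[g].end(), p2[g].begin() + d[g], p2[g].end());
    // offspring2 = left(p2) + [end pad] + right(p1)
    o2[g].reserve(Dmax + (W1 - cut));
    o2[g].insert(o2[g].end(), p2[g].begin(), p2[g].begin() + d[g]);
    o2[g].insert(o2[g].end(), Dmax - d[g], 0);
    o2[g].insert(o2[g].end(), p1[g].begin() + cut, p1[g].end());
  }
  normalize_masks(o1);
  normalize_masks(o2);
}

// One mutation event at (group g, position p). Gap position: extend the gap
// by one (prob 1/2) or remove it; EC position: insert a gap before it. Other
// groups are padded at the end to keep the chromosome rectangular.
void mutate_at(std::vector<std::vector<unsigned char>>& m, int g, int p) {
  const int G = (int)m.size();
  if (m[g][p] == 0) {
    if (unif_rand() < 0.5) {
      m[g].insert(m[g].begin() + p, 0);
      for (int h = 0; h < G; ++h)
        if (h != g) m[h].push_back(0);
    } else {
      m[g].erase(m[g].begin() + p);
      m[g].push_back(0);
    }
  } else {
    m[g].insert(m[g].begin() + p, 0);
    for (int h = 0; h < G; ++h)
      if (h != g) m[h].push_back(0);
  }
  normalize_masks(m);
}

void mutate_chrom(Chrom& ch, int policy, double rate) {
  const int G = (int)ch.masks.size();
  if (policy == 0) { // per_individual: one event, applied with prob `rate`
    if (rate < 1.0 && unif_rand() >= rate) return;
    int W = ch.width();
    int idx = runif_int(G * W);
    mutate_at(ch.masks, idx / W, idx % W);
    ch.evaluated = false;
  } else {           // per_position: Binomial(G*W, rate) independent events
    int W = ch.width();
    int n = (int)R::rbinom((double)(G * W), rate);
    for (int t = 0; t < n; ++t) {
      W = ch.width();
      int idx = runif_int(G * W);
      mutate_at(ch.masks, idx / W, idx % W);
    }
    if (n > 0) ch.evaluated = false;
  }
}

int tournament(const std::vector<Chrom>& pop, int tsize) {
  int best = runif_int((int)pop.size());
  for (int t = 1; t < tsize; ++t) {
    int c = runif_int((int)pop.size());
    if (pop[c].fit < pop[best].fit) best = c;
  }
  return best;
}

List chrom_to_list(const Chrom& ch) {
  List masks(ch.masks.size());
  for (size_t g = 0; g < ch.masks.size(); ++g) {
    IntegerVector v(ch.masks[g].size());
    for (size_t j = 0; j < ch.masks[g].size(); ++j) v[j] = ch.masks[g][j];
    masks[g] = v;
  }
  return List::create(_["masks"] = masks,
                      _["objective"] = ch.fit,
                      _["homogeneity"] = ch.hom,
                      _["gap_penalty"] = ch.gc,
                      _["column_increment"] = ch.ci);
}

} // namespace

// [[Rcpp::export]]
List cpp_score_masks(List blocks, List masks, IntegerMatrix levels,
                     double w1, double w2, double w3,
                     int gc_mode, int ci_mode, int norm_mode) {
  Problem P = make_problem(blocks, levels, w1, w2, w3, gc_mode, ci_mode, norm_mode);
  Chrom ch;
  ch.masks.resize(masks.size());
  for (int g = 0; g < masks.size(); ++g) {
    IntegerVector v = masks[g];
    ch.masks[g].assign(v.begin(), v.end());
  }
  ScoreBuf buf;
  score_chrom(P, ch, buf);
  return chrom_to_list(ch);
}

// [[Rcpp::export]]
List cpp_crossover(List masks1, List masks2, int cut) {
  std::vector<std::vector<unsigned char>> p1(masks1.size()), p2(masks2.size());
  for (int g = 0; g < masks1.size(); ++g) {
    IntegerVector a = masks1[g], b = masks2[g];
    p1[g].assign(a.begin(), a.end());
    p2[g].assign(b.begin(), b.end());
  }
  std::vector<std::vector<unsigned char>> o1, o2;
  crossover_masks(p1, p2, cut, o1, o2);
  List r1(o1.size()), r2(o2.size());
  for (size_t g = 0; g < o1.size(); ++g) {
    r1[g] = IntegerVector(o1[g].begin(), o1[g].end());
    r2[g] = IntegerVector(o2[g].begin(), o2[g].end());
  }
  return List::create(_["offspring1"] = r1, _["offspring2"] = r2);
}

// [[Rcpp::export]]
List cpp_mutate(List masks, int policy, double rate) {
  std::vector<std::vector<unsigned char>> m(masks.size());
  for (int g = 0; g < masks.size(); ++g) {
    IntegerVector v = masks[g];
    m[g].assign(v.begin(), v.end());
  }
  Chrom ch;
  ch.masks = std::move(m);
  mutate_chrom(ch, policy, rate);
  List out(ch.masks.size());
  for (size_t g = 0; g < ch.masks.size(); ++g)
    out[g] = IntegerVector(ch.masks[g].begin(), ch.masks[g].end());
  return out;
}

// [[Rcpp::export]]
List cpp_ga_run(List blocks, IntegerMatrix levels,
                int pop_size, double crossover_rate, int mutation_policy,
                double mutation_rate, int tournament_size,
                int stagnation_generations, int max_extra_columns,
                bool seed_trivial,
                double w1, double w2, double w3,
                int gc_mode, int ci_mode, int norm_mode,
                int max_generations) {
  Problem P = make_problem(blocks, levels, w1, w2, w3, gc_mode, ci_mode, norm_mode);
  ScoreBuf buf;

  std::vector<Chrom> pop;
  pop.reserve(pop_size);
  for (int i = 0; i < pop_size; ++i)
    pop.push_back(random_chrom(P, max_extra_columns));
  if (seed_trivial && pop_size > 0)
    pop[0] = trivial_chrom(P);
  for (auto& ch : pop) score_chrom(P, ch, buf);

  int best_i = 0;
  for (int i = 1; i < pop_size; ++i)
    if (pop[i].fit < pop[best_i].fit) best_i = i;
  Chrom best = pop[best_i];

  int stag = 0, gen = 0;
  std::vector<Chrom> newpop(pop_size);
  std::vector<std::vector<unsigned char>> o1buf, o2buf;
  while (stag < stagnation_generations && gen < max_generations) {
    ++gen;
    newpop[0] = best; // elitism
    int filled = 1;
    while (filled < pop_size) {
      const Chrom& p1 = pop[tournament(pop, tournament_size)];
      const Chrom& p2 = pop[tournament(pop, tournament_size)];
      int W1 = p1.width();
      if (unif_rand() < crossover_rate && W1 >= 2) {
        int cut = 1 + runif_int(W1 - 1);
        crossover_masks(p1.masks, p2.masks, cut, o1buf, o2buf);
        // offspring identical to a parent inherit its fitness unevaluated
        for (int k = 0; k < 2 && filled < pop_size; ++k) {
          const std::vector<std::vector<unsigned char>>& ob =
              (k == 0) ? o1buf : o2buf;
          Chrom& slot = newpop[filled++];
          slot.masks = ob;
          if (ob == p1.masks) {
            slot.fit = p1.fit; slot.hom = p1.hom; slot.gc = p1.gc;
            slot.ci = p1.ci; slot.evaluated = true;
          } else if (ob == p2.masks) {
            slot.fit = p2.fit; slot.hom = p2.hom; slot.gc = p2.gc;
            slot.ci = p2.ci; slot.evaluated = true;
          } else {
            slot.evaluated = false;
          }
        }
      } else {
        newpop[filled++] = p1;
        if (filled < pop_size) newpop[filled++] = p2;
      }
    }
    for (int i = 1; i < pop_size; ++i)
      mutate_chrom(newpop[i], mutation_policy, mutation_rate);
    for (auto& ch : newpop)
      if (!ch.evaluated) score_chrom(P, ch, buf);
    pop.swap(newpop);
    int gb = 0;
    for (int i = 1; i < pop_size; ++i)
      if (pop[i].fit < pop[gb].fit) gb = i;
    if (pop[gb].fit < best.fit - 1e-12) {
      best = pop[gb];
      stag = 0;
    } else {
      ++stag;
    }
  }
  List out = chrom_to_list(best);
  out["generations"] = gen;
  return out;
}

// Exhaustive oracle over every gap placement of two sequences up to
// max_width; widths are scanned in increasing order and improvements must be
// strict, so ties resolve to fewest columns then lexicographically smallest
// gap pattern of sequence A then B.
// [[Rcpp::export]]
List cpp_brute_force(IntegerVector seqA, IntegerVector seqB,
                     IntegerMatrix levels, int max_width,
                     double w1, double w2, double w3,
                     int gc_mode, int ci_mode, int norm_mode) {
  const int la = seqA.size(), lb = seqB.size();
  List blocks = List::create(
      IntegerMatrix(1, la, seqA.begin()),
      IntegerMatrix(1, lb, seqB.begin()));
  Problem P = make_problem(blocks, levels, w1, w2, w3, gc_mode, ci_mode, norm_mode);
  ScoreBuf buf;

  Chrom best;
  best.fit = R_PosInf;
  Chrom cur;
  cur.masks.assign(2, {});

  int wmin = std::max(la, lb);
  for (int w = wmin; w <= max_width; ++w) {
    // positions of the 1s in mask A: combination vector a[0..la-1]
    std::vector<int> a(la), b(lb);
    std::vector<unsigned char> maskA(w), maskB(w);
    for (int i = 0; i < la; ++i) a[i] = i;
    bool more_a = true;
    while (more_a) {
      std::fill(maskA.begin(), maskA.end(), 0);
      for (int i = 0; i < la; ++i) maskA[a[i]] = 1;
      for (int i = 0; i < lb; ++i) b[i] = i;
      bool more_b = true;
      while (more_b) {
        std::fill(maskB.begin(), maskB.end(), 0);
        for (int i = 0; i < lb; ++i) maskB[b[i]] = 1;
        bool allgap = false;
        for (int j = 0; j < w; ++j)
          if (!maskA[j] && !maskB[j]) { allgap = true; break; }
        if (!allgap) {
          cur.masks[0].assign(maskA.begin(), maskA.end());
          cur.masks[1].assign(maskB.begin(), maskB.end());
          score_chrom(P, cur, buf);
          if (cur.fit < best.fit - 1e-15) best = cur;
        }
        // next combination for b
        int i = lb - 1;
        while (i >= 0 && b[i] == w - lb + i) --i;
        if (i < 0) more_b = false;
        else { ++b[i]; for (int j = i + 1; j < lb; ++j) b[j] = b[j - 1] + 1; }
      }
      int i = la - 1;
      while (i >= 0 && a[i] == w - la + i) --i;
      if (i < 0) more_a = false;
      else { ++a[i]; for (int j = i + 1; j < la; ++j) a[j] = a[j - 1] + 1; }
    }
  }
  return chrom_to_list(best);
}
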