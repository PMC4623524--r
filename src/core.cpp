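// Low-level sequence kernels: canonical k-mer counting, unitig extraction
// with graph cleanup, a seed-and-extend read mapper with soft clipping,
// pileup accumulation and string overlap helpers.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <map>
#include <string>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string rc_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Index of the lexicographically least rotation (direct comparison on the
// doubled string; early exit keeps this near-linear on non-periodic input).
static size_t least_rotation_idx(const std::string& s) {
  size_t n = s.size();
  if (n <= 1) return 0;
  std::string t = s + s;
  size_t best = 0;
  for (size_t i = 1; i < n; ++i) {
    for (size_t j = 0; j < n; ++j) {
      char a = t[i + j], b = t[best + j];
      if (a < b) { best = i; break; }
      if (a > b) break;
    }
  }
  return best;
}

static std::string least_rotation(const std::string& s) {
  if (s.empty()) return s;
  size_t i = least_rotation_idx(s);
  return s.substr(i) + s.substr(0, i);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return rc_str(s); }

// Canonical form of a circular sequence: least rotation over both strands.
// [[Rcpp::export]]
std::string cpp_canonical_circular(std::string s) {
  std::string a = least_rotation(s);
  std::string b = least_rotation(rc_str(s));
  return a < b ? a : b;
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) return -1;
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}

// ---------------------------------------------------------------------------
// k-mer counting
// ---------------------------------------------------------------------------

static void count_into(const std::string& s, int k,
                       std::unordered_map<std::string, int>& tab) {
  int n = (int)s.size();
  if (n < k) return;
  int last_bad = -1;  // most recent invalid base position
  for (int i = 0; i < n; ++i) if (!valid_base(s[i]) && i < k - 1) last_bad = i;
  for (int i = 0; i + k <= n; ++i) {
    if (i == 0) {
      last_bad = -1;
      for (int j = 0; j < k; ++j) if (!valid_base(s[j])) last_bad = j;
    } else if (!valid_base(s[i + k - 1])) {
      last_bad = i + k - 1;
    }
    if (last_bad >= i) continue;
    std::string km = s.substr(i, k);
    std::string rcm = rc_str(km);
    tab[km < rcm ? km : rcm]++;
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, int min_count) {
  std::unordered_map<std::string, int> tab;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    count_into(s, k, tab);
  }
  std::vector<std::pair<std::string, int>> out;
  out.reserve(tab.size());
  for (auto& kv : tab) if (kv.second >= min_count) out.push_back(kv);
  std::sort(out.begin(), out.end());
  CharacterVector km(out.size());
  IntegerVector ct(out.size());
  for (size_t i = 0; i < out.size(); ++i) { km[i] = out[i].first; ct[i] = out[i].second; }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// ---------------------------------------------------------------------------
// Unitig extraction with tip / bubble / relative-abundance cleanup
// ---------------------------------------------------------------------------

struct DBG {
  int k;
  std::vector<std::string> kmers;
  std::vector<int> cnt;
  std::vector<char> alive;
  std::unordered_map<std::string, int> idx;

  std::string oriented(int id, int strand) const {
    return strand == 0 ? kmers[id] : rc_str(kmers[id]);
  }
  // successors of node (id,strand) in its oriented reading
  std::vector<std::pair<int,int>> nexts(int id, int strand) const {
    std::vector<std::pair<int,int>> out;
    std::string S = oriented(id, strand);
    std::string core = S.substr(1);
    static const char B[4] = {'A','C','G','T'};
    for (int b = 0; b < 4; ++b) {
      std::string T = core + B[b];
      std::string R = rc_str(T);
      const std::string& canon = T < R ? T : R;
      auto it = idx.find(canon);
      if (it != idx.end() && alive[it->second])
        out.push_back({it->second, canon == T ? 0 : 1});
    }
    return out;
  }
  std::vector<std::pair<int,int>> prevs(int id, int strand) const {
    // predecessors = revcomp of successors of the revcomp orientation
    std::vector<std::pair<int,int>> out;
    for (auto& p : nexts(id, 1 - strand)) out.push_back({p.first, 1 - p.second});
    return out;
  }
};

struct Unitig {
  std::vector<std::pair<int,int>> path;  // (id, strand)
  bool circular;
  std::string seq;       // path orientation
  double mean_count;
};

static std::string spell(const DBG& g, const std::vector<std::pair<int,int>>& path) {
  std::string s = g.oriented(path[0].first, path[0].second);
  for (size_t i = 1; i < path.size(); ++i)
    s.push_back(g.oriented(path[i].first, path[i].second).back());
  return s;
}

static std::vector<Unitig> extract_unitigs(const DBG& g) {
  int n = (int)g.kmers.size();
  std::vector<char> visited(n, 0);
  std::vector<Unitig> out;
  for (int start = 0; start < n; ++start) {
    if (!g.alive[start] || visited[start]) continue;
    std::vector<std::pair<int,int>> path;
    path.push_back({start, 0});
    visited[start] = 1;
    bool circular = false;
    // forward
    std::pair<int,int> cur = {start, 0};
    while (true) {
      auto ns = g.nexts(cur.first, cur.second);
      if (ns.size() != 1) break;
      auto nx = ns[0];
      auto ps = g.prevs(nx.first, nx.second);
      if (ps.size() != 1) break;
      if (nx.first == start) { if (nx.second == 0) circular = true; break; }
      if (visited[nx.first]) break;
      path.push_back(nx);
      visited[nx.first] = 1;
      cur = nx;
    }
    if (!circular) {
      // backward from start
      cur = {start, 0};
      std::vector<std::pair<int,int>> pre;
      while (true) {
        auto ps = g.prevs(cur.first, cur.second);
        if (ps.size() != 1) break;
        auto pv = ps[0];
        auto ns = g.nexts(pv.first, pv.second);
        if (ns.size() != 1) break;
        if (pv.first == start || visited[pv.first]) break;
        pre.push_back(pv);
        visited[pv.first] = 1;
        cur = pv;
      }
      std::reverse(pre.begin(), pre.end());
      pre.insert(pre.end(), path.begin(), path.end());
      path.swap(pre);
    }
    Unitig u;
    u.path = path;
    u.circular = circular;
    u.seq = spell(g, path);
    double s = 0;
    for (auto& p : path) s += g.cnt[p.first];
    u.mean_count = s / path.size();
    out.push_back(std::move(u));
  }
  return out;
}

// one cleanup pass; returns number of killed unitigs
static int cleanup_pass(DBG& g, double tip_len_factor, double tip_frac,
                        double rel_frac, int bubble_mm) {
  std::vector<Unitig> us = extract_unitigs(g);
  int nu = (int)us.size();
  std::vector<int> owner(g.kmers.size(), -1);
  for (int i = 0; i < nu; ++i)
    for (auto& p : us[i].path) owner[p.first] = i;

  // neighbor unitigs at each end
  std::vector<std::vector<int>> nb_start(nu), nb_end(nu);
  for (int i = 0; i < nu; ++i) {
    if (us[i].circular) continue;
    auto& first = us[i].path.front();
    auto& last = us[i].path.back();
    for (auto& p : g.prevs(first.first, first.second))
      if (owner[p.first] != i) nb_start[i].push_back(owner[p.first]);
    for (auto& p : g.nexts(last.first, last.second))
      if (owner[p.first] != i) nb_end[i].push_back(owner[p.first]);
  }
  std::vector<char> kill(nu, 0);
  int k = g.k;
  // contaminant branch stubs run up to a couple of read lengths, so the
  // tip cap has an absolute floor
  double tip_len = std::max(tip_len_factor * k, 300.0);

  for (int i = 0; i < nu; ++i) {
    if (us[i].circular) continue;
    bool dead_start = nb_start[i].empty();
    bool dead_end = nb_end[i].empty();
    double max_nb = 0;
    for (int j : nb_start[i]) max_nb = std::max(max_nb, us[j].mean_count);
    for (int j : nb_end[i]) max_nb = std::max(max_nb, us[j].mean_count);
    // tip: dead at exactly one end, short and weak
    if ((dead_start != dead_end) && (double)us[i].seq.size() < tip_len &&
        max_nb > 0 && us[i].mean_count < tip_frac * max_nb)
      kill[i] = 1;
    // relative abundance: dominated by every neighbour
    if (!dead_start && !dead_end && max_nb > 0 &&
        us[i].mean_count < rel_frac * max_nb)
      kill[i] = 1;
  }

  // bubbles: same oriented entry/exit junction nodes, equal length,
  // few mismatches -> keep strongest
  std::map<std::string, std::vector<std::pair<int,std::string>>> groups;
  for (int i = 0; i < nu; ++i) {
    if (us[i].circular || kill[i]) continue;
    auto pv = g.prevs(us[i].path.front().first, us[i].path.front().second);
    auto nx = g.nexts(us[i].path.back().first, us[i].path.back().second);
    if (pv.size() != 1 || nx.size() != 1) continue;
    std::string e = g.oriented(pv[0].first, pv[0].second);
    std::string x = g.oriented(nx[0].first, nx[0].second);
    std::string fwd_key = e + "|" + x;
    std::string rev_key = rc_str(x) + "|" + rc_str(e);
    if (fwd_key <= rev_key) groups[fwd_key].push_back({i, us[i].seq});
    else groups[rev_key].push_back({i, rc_str(us[i].seq)});
  }
  for (auto& kv : groups) {
    auto& v = kv.second;
    if (v.size() < 2) continue;
    for (size_t a = 0; a < v.size(); ++a) {
      for (size_t b = a + 1; b < v.size(); ++b) {
        int ia = v[a].first, ib = v[b].first;
        if (kill[ia] || kill[ib]) continue;
        if (v[a].second.size() != v[b].second.size()) continue;
        int mm = 0;
        for (size_t t = 0; t < v[a].second.size(); ++t)
          if (v[a].second[t] != v[b].second[t]) ++mm;
        if (mm <= bubble_mm) {
          // drop the weaker branch (lexicographic seq breaks ties)
          bool drop_a = us[ia].mean_count < us[ib].mean_count ||
            (us[ia].mean_count == us[ib].mean_count && v[a].second > v[b].second);
          kill[drop_a ? ia : ib] = 1;
        }
      }
    }
  }

  int killed = 0;
  for (int i = 0; i < nu; ++i) {
    if (!kill[i]) continue;
    ++killed;
    for (auto& p : us[i].path) g.alive[p.first] = 0;
  }
  return killed;
}

// [[Rcpp::export]]
List cpp_unitigs(CharacterVector kmers, IntegerVector counts, int k,
                 int cleanup_rounds = 3, double tip_len_factor = 2.0,
                 double tip_frac = 0.25, double rel_frac = 0.05,
                 int bubble_mm = 2) {
  DBG g;
  g.k = k;
  int n = kmers.size();
  g.kmers.resize(n);
  g.cnt.resize(n);
  g.alive.assign(n, 1);
  for (int i = 0; i < n; ++i) {
    g.kmers[i] = as<std::string>(kmers[i]);
    g.cnt[i] = counts[i];
    g.idx[g.kmers[i]] = i;
  }
  for (int r = 0; r < cleanup_rounds; ++r)
    if (cleanup_pass(g, tip_len_factor, tip_frac, rel_frac, bubble_mm) == 0) break;

  std::vector<Unitig> us = extract_unitigs(g);
  // canonical output orientation
  std::vector<std::tuple<std::string,bool,double,int>> rows;
  for (auto& u : us) {
    std::string s;
    if (u.circular) {
      std::string core = u.seq.substr(0, u.seq.size() - (k - 1));
      s = cpp_canonical_circular(core);
    } else {
      std::string r = rc_str(u.seq);
      s = u.seq < r ? u.seq : r;
    }
    rows.push_back({s, u.circular, u.mean_count, (int)u.path.size()});
  }
  std::sort(rows.begin(), rows.end(), [](const auto& a, const auto& b) {
    if (std::get<0>(a).size() != std::get<0>(b).size())
      return std::get<0>(a).size() > std::get<0>(b).size();
    return std::get<0>(a) < std::get<0>(b);
  });
  CharacterVector seq(rows.size());
  LogicalVector circ(rows.size());
  NumericVector mc(rows.size());
  IntegerVector nk(rows.size());
  for (size_t i = 0; i < rows.size(); ++i) {
    seq[i] = std::get<0>(rows[i]);
    circ[i] = std::get<1>(rows[i]);
    mc[i] = std::get<2>(rows[i]);
    nk[i] = std::get<3>(rows[i]);
  }
  return List::create(_["seq"] = seq, _["circular"] = circ,
                      _["mean_count"] = mc, _["n_kmers"] = nk);
}

// ---------------------------------------------------------------------------
// Read mapping: exact seeds + gapless X-drop extension with soft clipping
// ---------------------------------------------------------------------------

static inline bool encode_kmer(const std::string& s, int pos, int len, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < len; ++i) {
    char c = s[pos + i];
    int b;
    switch (c) { case 'A': b = 0; break; case 'C': b = 1; break;
                 case 'G': b = 2; break; case 'T': b = 3; break;
                 default: return false; }
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

struct Hit { long diag; int strand; int qs, qe, mm; int score; };

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, std::string ref, bool circular,
                        double max_mm_rate, int seed_len = 15, int xdrop = 12,
                        bool require_full = false, int max_hits = 50,
                        int min_aln = 25) {
  long n = (long)ref.size();
  int max_rl = 0;
  for (R_xlen_t i = 0; i < reads.size(); ++i)
    max_rl = std::max(max_rl, (int)strlen(CHAR(STRING_ELT(reads, i))));
  std::string R = ref;
  if (circular && n > 0) R += ref.substr(0, std::min<long>(n, max_rl + 1));

  std::unordered_map<uint64_t, std::vector<long>> index;
  for (long p = 0; p + seed_len <= (long)R.size(); ++p) {
    uint64_t v;
    if (encode_kmer(R, p, seed_len, v)) index[v].push_back(p);
  }

  std::vector<int> o_q, o_rs, o_re, o_qs, o_qe, o_nm, o_nb;
  std::vector<std::string> o_strand;

  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int L = (int)fwd.size();
    if (L < seed_len || n < seed_len) continue;
    std::string rev = rc_str(fwd);
    std::vector<Hit> best;
    int best_score = 0;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? fwd : rev;
      std::vector<int> offs;
      offs.push_back(0);
      if (L >= 2 * seed_len) offs.push_back((L - seed_len) / 2);
      if (L >= seed_len) offs.push_back(L - seed_len);
      std::unordered_set<long> seen;
      for (int off : offs) {
        uint64_t v;
        if (!encode_kmer(q, off, seed_len, v)) continue;
        auto it = index.find(v);
        if (it == index.end()) continue;
        if (it->second.size() > 200) continue;  // uninformative seed
        for (long p : it->second) {
          long d = p - off;  // ref position of read base 0 on this diagonal
          if (circular) {
            long dm = ((d % n) + n) % n;
            // anchor must start within original ref
            if (p >= n + max_rl) continue;
            d = dm;
          }
          if (!seen.insert(d * 2 + strand).second) continue;
          // extend around the seed
          long base = d;
          int anchor = off;
          // rightwards from anchor
          int sc = 0, best_r = anchor, sc_r = 0, cur = 0, mm_run = 0;
          std::vector<char> match(L, 0);
          for (int i = anchor; i < L; ++i) {
            long rp = base + i;
            char rb;
            if (circular) rb = R[rp % n + (rp % n < 0 ? n : 0)];
            else { if (rp < 0 || rp >= n) break; rb = R[rp]; }
            bool m = (rb == q[i]) && valid_base(q[i]) && valid_base(rb);
            match[i] = m;
            cur += m ? 1 : -3;
            if (cur > sc_r) { sc_r = cur; best_r = i + 1; }
            if (sc_r - cur > xdrop) break;
            (void)mm_run;
          }
          // leftwards
          int best_l = anchor, sc_l = 0;
          cur = 0;
          for (int i = anchor - 1; i >= 0; --i) {
            long rp = base + i;
            char rb;
            if (circular) rb = R[rp % n + (rp % n < 0 ? n : 0)];
            else { if (rp < 0 || rp >= n) break; rb = R[rp]; }
            bool m = (rb == q[i]) && valid_base(q[i]) && valid_base(rb);
            match[i] = m;
            cur += m ? 1 : -3;
            if (cur > sc_l) { sc_l = cur; best_l = i; }
            if (sc_l - cur > xdrop) break;
          }
          int qs = best_l, qe = best_r;
          if (qe <= qs) continue;
          int mm = 0;
          for (int i = qs; i < qe; ++i) if (!match[i]) ++mm;
          int alen = qe - qs;
          sc = (alen - mm) - 3 * mm;
          if (require_full && (qs != 0 || qe != L || mm != 0)) continue;
          if (alen < std::min(min_aln, L)) continue;
          if (mm > max_mm_rate * alen) continue;
          if (sc <= 0) continue;
          if (sc > best_score) { best_score = sc; best.clear(); }
          if (sc == best_score) best.push_back({d, strand, qs, qe, mm, sc});
        }
      }
    }
    if (best.empty()) continue;
    // dedupe and order deterministically
    std::sort(best.begin(), best.end(), [](const Hit& a, const Hit& b) {
      if (a.diag != b.diag) return a.diag < b.diag;
      return a.strand < b.strand;
    });
    best.erase(std::unique(best.begin(), best.end(), [](const Hit& a, const Hit& b) {
      return a.diag == b.diag && a.strand == b.strand;
    }), best.end());
    int nb = (int)best.size();
    int emit = std::min(nb, max_hits);
    for (int i = 0; i < emit; ++i) {
      Hit& h = best[i];
      long rs = h.diag + h.qs, re = h.diag + h.qe;
      if (circular) {
        long m = ((rs % n) + n) % n;
        re = m + (re - rs);
        rs = m;
      }
      o_q.push_back((int)ri + 1);
      o_rs.push_back((int)rs);
      o_re.push_back((int)re);
      o_qs.push_back(h.qs);
      o_qe.push_back(h.qe);
      o_nm.push_back(h.mm);
      o_nb.push_back(nb);
      o_strand.push_back(h.strand == 0 ? "+" : "-");
    }
  }
  return DataFrame::create(
    _["qidx"] = o_q, _["rstart"] = o_rs, _["rend"] = o_re,
    _["qstart"] = o_qs, _["qend"] = o_qe, _["strand"] = o_strand,
    _["nm"] = o_nm, _["n_best"] = o_nb,
    _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Pileup: per-position A/C/G/T/N counts from aligned (unclipped) segments
// ---------------------------------------------------------------------------

// oriented: read sequence in the orientation it aligned (already revcomp'd
// for minus-strand placements)
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(IntegerVector rstart, IntegerVector qstart,
                         IntegerVector qend, CharacterVector oriented,
                         int reflen, bool circular) {
  IntegerMatrix M(5, reflen);
  int n = rstart.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(oriented[i]);
    for (int j = qstart[i]; j < qend[i]; ++j) {
      long p = (long)rstart[i] + (j - qstart[i]);
      if (circular) p = ((p % reflen) + reflen) % reflen;
      else if (p < 0 || p >= reflen) continue;
      int row;
      switch (s[j]) { case 'A': row = 0; break; case 'C': row = 1; break;
                      case 'G': row = 2; break; case 'T': row = 3; break;
                      default: row = 4; }
      M(row, p)++;
    }
  }
  return M;
}

// ---------------------------------------------------------------------------
// Overlap helpers
// ---------------------------------------------------------------------------

// Longest L such that the last L chars of a equal the first L chars of b.
// Exact; O(|a|+|b|) via prefix function on b#a.
// [[Rcpp::export]]
int cpp_max_overlap(std::string a, std::string b, int min_ov = 1, int cap = 0) {
  if (cap > 0) {
    if ((int)a.size() > cap) a = a.substr(a.size() - cap);
    if ((int)b.size() > cap) b = b.substr(0, cap);
  }
  size_t maxl = std::min(a.size(), b.size());
  if (maxl == 0) return 0;
  std::string s = b + '\x01' + a;
  std::vector<int> pi(s.size(), 0);
  for (size_t i = 1; i < s.size(); ++i) {
    int j = pi[i - 1];
    while (j > 0 && s[i] != s[j]) j = pi[j - 1];
    if (s[i] == s[j]) ++j;
    pi[i] = j;
  }
  int L = pi.back();
  if (L > (int)maxl) L = (int)maxl;
  return L >= min_ov ? L : 0;
}

// Longest L (<= cap) with suffix_L(a) ~ prefix_L(b) at <= mm_frac mismatches.
// [[Rcpp::export]]
int cpp_max_overlap_mm(std::string a, std::string b, int min_ov,
                       double mm_frac, int cap = 600) {
  int maxl = (int)std::min({a.size(), b.size(), (size_t)cap});
  for (int L = maxl; L >= min_ov; --L) {
    int allowed = (int)(mm_frac * L);
    int mm = 0;
    const char* pa = a.data() + a.size() - L;
    bool ok = true;
    for (int i = 0; i < L; ++i) {
      if (pa[i] != b[i] && ++mm > allowed) { ok = false; break; }
    }
    if (ok) return L;
  }
  return 0;
}

// [[Rcpp::export]]
IntegerVector cpp_max_overlap_vec(std::string a, CharacterVector bs,
                                  int min_ov = 1, int cap = 0) {
  IntegerVector out(bs.size());
  for (R_xlen_t i = 0; i < bs.size(); ++i)
    out[i] = cpp_max_overlap(a, as<std::string>(bs[i]), min_ov, cap);
  return out;
}
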