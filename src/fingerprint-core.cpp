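// Low-level kernels for fingerprint generation: FNV-1a hashing of integer
// rows and strings, iterative Morgan (circular) identifier refinement, and
// enumeration of canonical linear paths through a molecular graph.
#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <string>
#include <vector>
using namespace Rcpp;

static inline uint32_t fnv_mix(uint32_t h, uint32_t x) {
  for (int i = 0; i < 4; ++i) {
    h ^= (x >> (8 * i)) & 0xFFu;
    h *= 16777619u;
  }
  return h;
}

static inline uint32_t fnv_init() { return 2166136261u; }

// [[Rcpp::export]]
NumericVector cpp_hash_int_rows(IntegerMatrix m) {
  int n = m.nrow(), k = m.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    uint32_t h = fnv_init();
    for (int j = 0; j < k; ++j) h = fnv_mix(h, (uint32_t)m(i, j));
    out[i] = (double)h;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hash_strings(CharacterVector s) {
  int n = s.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    uint32_t h = fnv_init();
    const char *p = CHAR(STRING_ELT(s, i));
    for (; *p; ++p) {
      h ^= (uint32_t)(unsigned char)(*p);
      h *= 16777619u;
    }
    out[i] = (double)h;
  }
  return out;
}

// Iterative Morgan refinement.  init: per-atom initial identifiers (uint32
// stored in doubles); bonds: two-column 1-based matrix; btype: per-bond
// integer type code.  Returns an n_atom x (n_iter + 1) matrix of identifiers,
// column r holding the radius-r environment identifier of each atom.
// [[Rcpp::export]]
NumericMatrix cpp_morgan_ids(int n_atoms, NumericVector init,
                             IntegerMatrix bonds, IntegerVector btype,
                             int n_iter) {
  std::vector<std::vector<std::pair<int, int> > > adj(n_atoms);
  int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    int a1 = bonds(b, 0) - 1, a2 = bonds(b, 1) - 1;
    adj[a1].push_back(std::make_pair(a2, btype[b]));
    adj[a2].push_back(std::make_pair(a1, btype[b]));
  }
  NumericMatrix out(n_atoms, n_iter + 1);
  std::vector<uint32_t> cur(n_atoms), nxt(n_atoms);
  for (int a = 0; a < n_atoms; ++a) {
    cur[a] = (uint32_t)init[a];
    out(a, 0) = (double)cur[a];
  }
  std::vector<std::pair<uint32_t, uint32_t> > nb_ids;
  for (int it = 1; it <= n_iter; ++it) {
    for (int a = 0; a < n_atoms; ++a) {
      nb_ids.clear();
      for (size_t j = 0; j < adj[a].size(); ++j)
        nb_ids.push_back(std::make_pair((uint32_t)adj[a][j].second,
                                        cur[adj[a][j].first]));
      std::sort(nb_ids.begin(), nb_ids.end());
      uint32_t h = fnv_init();
      h = fnv_mix(h, (uint32_t)it);
      h = fnv_mix(h, cur[a]);
      for (size_t j = 0; j < nb_ids.size(); ++j) {
        h = fnv_mix(h, nb_ids[j].first);
        h = fnv_mix(h, nb_ids[j].second);
      }
      nxt[a] = h;
      out(a, it) = (double)h;
    }
    cur = nxt;
  }
  return out;
}

struct PathState {
  std::vector<int> atoms;
  std::vector<int> bonds;
};

// Enumerate all simple linear paths with up to max_bonds bonds (single atoms
// included).  Each path is rendered as alternating atom and bond labels; the
// lexicographically smaller of the forward and reverse rendering is kept.
// Returns the set of unique canonical path strings.
// [[Rcpp::export]]
CharacterVector cpp_path_strings(int n_atoms, IntegerMatrix bonds,
                                 CharacterVector atom_label,
                                 CharacterVector bond_label, int max_bonds) {
  std::vector<std::vector<std::pair<int, int> > > adj(n_atoms);
  int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    int a1 = bonds(b, 0) - 1, a2 = bonds(b, 1) - 1;
    adj[a1].push_back(std::make_pair(a2, b));
    adj[a2].push_back(std::make_pair(a1, b));
  }
  std::vector<std::string> alab(n_atoms);
  for (int a = 0; a < n_atoms; ++a) alab[a] = as<std::string>(atom_label[a]);
  std::vector<std::string> blab(nb);
  for (int b = 0; b < nb; ++b) blab[b] = as<std::string>(bond_label[b]);

  std::unordered_set<std::string> seen;
  std::vector<int> patoms, pbonds;
  std::vector<bool> onpath(n_atoms, false);

  // iterative DFS with explicit stack of (atom, next-neighbour-index)
  for (int start = 0; start < n_atoms; ++start) {
    patoms.assign(1, start);
    pbonds.clear();
    std::fill(onpath.begin(), onpath.end(), false);
    onpath[start] = true;
    std::vector<size_t> iter(1, 0);
    // record the single-atom path
    seen.insert(alab[start]);
    while (!iter.empty()) {
      int a = patoms.back();
      if (iter.back() < adj[a].size() && (int)pbonds.size() < max_bonds) {
        std::pair<int, int> nx = adj[a][iter.back()];
        ++iter.back();
        if (onpath[nx.first]) continue;
        patoms.push_back(nx.first);
        pbonds.push_back(nx.second);
        onpath[nx.first] = true;
        iter.push_back(0);
        // render forward and reverse
        std::string fwd, rev;
        int m = (int)patoms.size();
        for (int i = 0; i < m; ++i) {
          if (i > 0) fwd += blab[pbonds[i - 1]];
          fwd += alab[patoms[i]];
        }
        for (int i = m - 1; i >= 0; --i) {
          if (i < m - 1) rev += blab[pbonds[i]];
          rev += alab[patoms[i]];
        }
        seen.insert(fwd < rev ? fwd : rev);
      } else {
        onpath[a] = false;
        patoms.pop_back();
        if (!pbonds.empty()) pbonds.pop_back();
        iter.pop_back();
      }
    }
  }
  CharacterVector out(seen.size());
  int i = 0;
  for (std::unordered_set<std::string>::iterator it = seen.begin();
       it != seen.end(); ++it)
    out[i++] = *it;
  return out;
}
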