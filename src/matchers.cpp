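#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <string>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; 4 marks N / anything non-ACGT. N never matches anything.
static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return 4;
    }
}

static std::vector<int8_t> encode(const std::string& s) {
    std::vector<int8_t> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t)base_code(s[i]);
    return v;
}

// seed-and-extend ungapped HSP search on the plus strand of `subject`
// (caller handles the reverse complement).  Coordinates returned 1-based
// inclusive.  xdrop terminates an extension once the running score falls
// `xdrop` below the best score seen in that direction.
// [[Rcpp::export(name = ".cpp_find_hsps")]]
DataFrame cpp_find_hsps(std::string query, std::string subject,
                        int word_size, int match_score, int mismatch_score,
                        int xdrop, int min_score) {
    if (word_size < 4 || word_size > 31) stop("word_size must be in [4, 31]");
    std::vector<int8_t> q = encode(query), s = encode(subject);
    const long nq = (long)q.size(), ns = (long)s.size();
    std::vector<long> qs_out, qe_out, ss_out, se_out;
    std::vector<int> sc_out, id_out;
    if (nq < word_size || ns < word_size)
        return DataFrame::create(_["qStart"] = qs_out, _["qEnd"] = qe_out,
                                 _["sStart"] = ss_out, _["sEnd"] = se_out,
                                 _["score"] = sc_out, _["identities"] = id_out);

    // index all clean (N-free) words of the subject
    std::unordered_map<uint64_t, std::vector<long> > index;
    index.reserve((size_t)ns);
    {
        uint64_t key = 0; int run = 0;
        const uint64_t mask = (word_size == 32) ? ~0ULL
            : ((1ULL << (2 * word_size)) - 1);
        for (long j = 0; j < ns; ++j) {
            if (s[j] > 3) { run = 0; key = 0; continue; }
            key = ((key << 2) | (uint64_t)s[j]) & mask;
            if (++run >= word_size) index[key].push_back(j - word_size + 1);
        }
    }

    // per-diagonal rightmost query end already visited by an extension
    std::unordered_map<long, long> diag_extent;
    std::set<std::tuple<long, long, long> > seen;

    uint64_t key = 0; int run = 0;
    const uint64_t mask = (1ULL << (2 * word_size)) - 1;
    for (long i = 0; i < nq; ++i) {
        if (q[i] > 3) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)q[i]) & mask;
        if (++run < word_size) continue;
        long qi = i - word_size + 1;
        auto hit = index.find(key);
        if (hit == index.end()) continue;
        for (long sj : hit->second) {
            long diag = qi - sj;
            auto ext = diag_extent.find(diag);
            if (ext != diag_extent.end() && qi <= ext->second) continue;

            // extend left of the seed
            long best_left = 0; int run_sc = 0, best_sc_l = 0;
            {
                long a = qi - 1, b = sj - 1, off = 1;
                while (a >= 0 && b >= 0) {
                    run_sc += (q[a] == s[b] && q[a] <= 3) ? match_score
                                                          : mismatch_score;
                    if (run_sc > best_sc_l) { best_sc_l = run_sc; best_left = off; }
                    else if (best_sc_l - run_sc >= xdrop) break;
                    --a; --b; ++off;
                }
            }
            // extend right of the seed
            long best_right = 0; int best_sc_r = 0;
            {
                long a = qi + word_size, b = sj + word_size, off = 1;
                run_sc = 0;
                while (a < nq && b < ns) {
                    run_sc += (q[a] == s[b] && q[a] <= 3) ? match_score
                                                          : mismatch_score;
                    if (run_sc > best_sc_r) { best_sc_r = run_sc; best_right = off; }
                    else if (best_sc_r - run_sc >= xdrop) break;
                    ++a; ++b; ++off;
                }
            }
            long hq0 = qi - best_left, hq1 = qi + word_size - 1 + best_right;
            long hs0 = sj - best_left;
            diag_extent[diag] = hq1;
            int score = word_size * match_score + best_sc_l + best_sc_r;
            if (score < min_score) continue;
            if (!seen.insert(std::make_tuple(hq0, hq1, hs0)).second) continue;
            int ident = 0;
            for (long t = 0; t <= hq1 - hq0; ++t)
                if (q[hq0 + t] == s[hs0 + t] && q[hq0 + t] <= 3) ++ident;
            qs_out.push_back(hq0 + 1); qe_out.push_back(hq1 + 1);
            ss_out.push_back(hs0 + 1); se_out.push_back(hs0 + (hq1 - hq0) + 1);
            sc_out.push_back(score); id_out.push_back(ident);
        }
    }
    return DataFrame::create(_["qStart"] = qs_out, _["qEnd"] = qe_out,
                             _["sStart"] = ss_out, _["sEnd"] = se_out,
                             _["score"] = sc_out, _["identities"] = id_out);
}

// maximal exact matches of length >= min_length between query and the plus
// strand of `subject`; uniqueness filtering happens in R.  Coordinates
// 1-based inclusive.
// [[Rcpp::export(name = ".cpp_find_mems")]]
DataFrame cpp_find_mems(std::string query, std::string subject, int min_length) {
    if (min_length < 1) stop("min_length must be >= 1");
    const long nq = (long)query.size(), ns = (long)subject.size();
    std::vector<int8_t> q = encode(query), s = encode(subject);
    std::vector<long> qs_out, ss_out, len_out;
    if (nq < min_length || ns < min_length)
        return DataFrame::create(_["qStart"] = qs_out, _["sStart"] = ss_out,
                                 _["length"] = len_out);

    std::unordered_map<std::string, std::vector<long> > index;
    index.reserve((size_t)ns);
    for (long j = 0; j + min_length <= ns; ++j) {
        bool clean = true;
        for (long t = 0; t < min_length; ++t)
            if (s[j + t] > 3) { clean = false; break; }
        if (clean) index[subject.substr(j, min_length)].push_back(j);
    }

    std::unordered_map<long, long> diag_extent;
    std::set<std::pair<long, long> > seen;
    for (long i = 0; i + min_length <= nq; ++i) {
        bool clean = true;
        for (long t = 0; t < min_length; ++t)
            if (q[i + t] > 3) { clean = false; break; }
        if (!clean) continue;
        auto hit = index.find(query.substr(i, min_length));
        if (hit == index.end()) continue;
        for (long sj : hit->second) {
            long diag = i - sj;
            auto ext = diag_extent.find(diag);
            if (ext != diag_extent.end() && i <= ext->second) continue;
            long a = i - 1, b = sj - 1;
            while (a >= 0 && b >= 0 && q[a] == s[b] && q[a] <= 3) { --a; --b; }
            long qstart = a + 1, sstart = b + 1;
            a = i + min_length; b = sj + min_length;
            while (a < nq && b < ns && q[a] == s[b] && q[a] <= 3) { ++a; ++b; }
            long len = a - qstart;
            diag_extent[diag] = a - 1;
            if (seen.insert(std::make_pair(qstart, sstart)).second) {
                qs_out.push_back(qstart + 1);
                ss_out.push_back(sstart + 1);
                len_out.push_back(len);
            }
        }
    }
    return DataFrame::create(_["qStart"] = qs_out, _["sStart"] = ss_out,
                             _["length"] = len_out);
}

// overlapping occurrence count of `pattern` in `text`
// [[Rcpp::export(name = ".cpp_count_sub")]]
int cpp_count_sub(std::string text, std::string pattern) {
    if (pattern.empty() || pattern.size() > text.size()) return 0;
    int n = 0;
    size_t pos = text.find(pattern, 0);
    while (pos != std::string::npos) {
        ++n;
        pos = text.find(pattern, pos + 1);
    }
    return n;
}
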