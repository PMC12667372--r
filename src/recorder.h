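#pragma once
#include <vector>

// Access-trace recorder backing the obliviousness harness.  Instrumented
// kernels emit (op, label, index) events when recording is enabled; for fixed
// public shapes the event stream must be identical across secret inputs.
namespace obli {

struct Recorder {
  bool enabled = false;
  std::vector<int> op, label, index;
  void clear() {
    op.clear();
    label.clear();
    index.clear();
  }
};

Recorder &recorder();

inline void rec(int op, int lab, int idx) {
  Recorder &r = recorder();
  if (r.enabled) {
    r.op.push_back(op);
    r.label.push_back(lab);
    r.index.push_back(idx);
  }
}

enum { OP_READ = 1, OP_WRITE = 2, OP_SELECT = 3, OP_CMPX = 4, OP_DIV = 5, OP_SCAN = 6 };

} // namespace obli
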