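#include "recorder.h"

namespace obli {
Recorder &recorder() {
  static Recorder r;
  return r;
}
} // namespace obli
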