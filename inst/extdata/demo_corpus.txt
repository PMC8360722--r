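伤寒初感，始于太阳，故以发汗为先。
太阳初感，桂枝麻黄发汗。
甘草桂枝为先；麻黄附子细辛。
白术党参茯苓甘草。
杏仁桔梗麻黄；附子细辛甘草。
麦冬甘草太阳。
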