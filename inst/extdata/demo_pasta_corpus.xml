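<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic demonstration corpus (hand-written, not drawn from any
     released dataset): six short ESDs for a pasta-cooking scenario. -->
<scripts>
  <script scenario="cooking pasta" type="adapted" title="Cooking pasta">
    <esd id="d01" contributor="w1">
      <event>Put water in a pot</event>
      <event>Turn the stove on</event>
      <event>Boil the water</event>
      <event>Pour the noodles in</event>
      <event>Drain the pasta</event>
    </esd>
    <esd id="d02" contributor="w2">
      <event>Fill the pot</event>
      <event>Turn the burner on</event>
      <event>Boil water</event>
      <event>Pour the pasta in</event>
      <event>Stir them</event>
      <event>Drain the noodles</event>
    </esd>
    <esd id="d03" contributor="w3">
      <event>Put the water on</event>
      <event>Boil it</event>
      <event>Pour the spaghetti in</event>
      <event>Drain the pasta</event>
      <event>Serve the pasta</event>
    </esd>
    <esd id="d04" contributor="w4">
      <event>Put water in the pot</event>
      <event>Turn the stove on</event>
      <event>Boil the water</event>
      <event>Pour the pasta in</event>
      <event>Drain the pasta</event>
      <event>Serve the pasta</event>
    </esd>
    <esd id="d05" contributor="w5">
      <event>Put the water in</event>
      <event>Turn the hob on</event>
      <event>Boil the water</event>
      <event>Pour the noodles in</event>
      <event>Drain them</event>
    </esd>
    <esd id="d06" contributor="w6">
      <event>Put water in a pot</event>
      <event>Boil the water</event>
      <event>Pour the pasta in</event>
      <event>Stir the pasta</event>
      <event>Drain the pasta</event>
      <event>Serve the pasta</event>
    </esd>
  </script>
</scripts>
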